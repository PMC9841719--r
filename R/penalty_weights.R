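# Correlation-pattern dissimilarity and the Twiner/iTwiner penalty weights.
#
# For each gene j, its correlation profile in a group is the j-th column of
# that group's gene-gene correlation matrix. The angular dissimilarity
# between the two profiles,
#     d_j = arccos( <s_j^A, s_j^B> / (||s_j^A|| ||s_j^B||) ) in [0, pi],
# is large when the gene is co-expressed with different partners in the two
# classes. iTwiner penalizes each gene by q_j = max_k d_k / d_j >= 1, so the
# most differentially-correlated gene carries the smallest penalty (1) and
# genes with identical patterns (d_j = 0) are excluded outright (infinite
# penalty). The original Twiner uses w_j = d_j / max_k d_k directly, which
# instead favors genes with *similar* patterns.

#' Gene-gene correlation matrix within a sample group
#'
#' @param m Genes x samples expression matrix.
#' @param sample_ids Samples defining the group (>= 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Object of class `group_correlation`: list with `gene_ids` and
#'   `sigma`, a symmetric p x p matrix with unit diagonal. Genes constant
#'   within the group get zero correlation to all others (diagonal stays 1)
#'   with a warning.
#' @export
group_correlation <- function(m, sample_ids, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  validate_expression_matrix(m)
  sample_ids <- as.character(sample_ids)
  if (!all(sample_ids %in% colnames(m))) stop("sample IDs missing from matrix")
  if (length(sample_ids) < 3L) stop("at least 3 samples are required per group")
  sub <- m[, sample_ids, drop = FALSE]
  const <- apply(sub, 1L, function(x) max(x) == min(x))
  sigma <- suppressWarnings(stats::cor(t(sub), method = method))
  if (any(const)) {
    warning(sprintf("%d gene(s) constant within group; correlations set to 0: %s",
                    sum(const), paste(utils::head(rownames(m)[const], 5L), collapse = ", ")))
    sigma[const, ] <- 0
    sigma[, const] <- 0
  }
  diag(sigma) <- 1
  sigma <- (sigma + t(sigma)) / 2
  structure(list(gene_ids = rownames(m), sigma = sigma),
            class = "group_correlation")
}

#' Angular dissimilarity of correlation profiles between two groups
#'
#' @param sa,sb `group_correlation` objects over the same genes in the same
#'   order.
#' @param include_self Keep the self-correlation entry in each profile
#'   (profiles live in R^p). `FALSE` drops the j-th coordinate of profile j
#'   ("remaining genes only"); the difference is a shared +1 coordinate and
#'   is negligible for large p.
#' @return Named numeric vector `d` in `[0, pi]`, one entry per gene.
#' @export
angular_dissimilarity <- function(sa, sb, include_self = TRUE) {
  if (!inherits(sa, "group_correlation") || !inherits(sb, "group_correlation"))
    stop("inputs must be group_correlation objects")
  if (!identical(sa$gene_ids, sb$gene_ids))
    stop("gene IDs (and their order) must match between the two groups")
  A <- sa$sigma; B <- sb$sigma
  dot <- colSums(A * B)
  na2 <- colSums(A * A)
  nb2 <- colSums(B * B)
  if (!include_self) {
    dot <- dot - diag(A) * diag(B)
    na2 <- na2 - diag(A)^2
    nb2 <- nb2 - diag(B)^2
  }
  denom <- sqrt(na2) * sqrt(nb2)
  cosang <- ifelse(denom > 0, dot / denom, 1)
  cosang <- pmin(1, pmax(-1, cosang))  # absorb floating-point overshoot
  # snap to the poles: acos amplifies rounding near |cos| = 1 (an error of
  # machine epsilon in the cosine is ~1e-8 rad), so angles this close to
  # 0 or pi are rounding noise and identical profiles must give d = 0
  cosang[cosang > 1 - 1e-12] <- 1
  cosang[cosang < -(1 - 1e-12)] <- -1
  d <- acos(cosang)
  names(d) <- sa$gene_ids
  d
}

#' iTwiner penalty weights from dissimilarities
#'
#' Normalizes `d` to `w = d / max(d)` and inverts: `q = 1 / w >= 1`, so the
#' most dissimilar gene gets penalty 1 and similarity is penalized. Genes
#' with `d = 0` receive an infinite penalty (sentinel `Inf`) and are
#' excluded from any downstream fit.
#'
#' @param d Dissimilarity vector in `[0, pi]` with `max(d) > 0`.
#' @return Object of class `diss_weights`: list with `gene_ids`, `d`, `w`,
#'   `q`, `penalty` (the vector a solver should consume) and `type`.
#' @export
itwiner_weights <- function(d) {
  check_dissimilarity(d)
  w <- d / max(d)
  q <- ifelse(w > 0, 1 / w, Inf)
  structure(list(gene_ids = names(d), d = d, w = w, q = q,
                 penalty = q, type = "itwiner"),
            class = "diss_weights")
}

#' Twiner penalty weights (similarity-seeking original)
#'
#' Uses the normalized distances `w = d / max(d)` directly as the penalty:
#' genes with similar correlation patterns in the two groups (small `d`)
#' are penalized least. Provided for comparison with the inverse variant.
#'
#' @inheritParams itwiner_weights
#' @return `diss_weights` object with `penalty = w` and `type = "twiner"`.
#' @export
twiner_weights <- function(d) {
  check_dissimilarity(d)
  w <- d / max(d)
  q <- ifelse(w > 0, 1 / w, Inf)
  structure(list(gene_ids = names(d), d = d, w = w, q = q,
                 penalty = w, type = "twiner"),
            class = "diss_weights")
}

check_dissimilarity <- function(d) {
  if (!length(d) || any(!is.finite(d)) || any(d < 0) || any(d > pi + 1e-12))
    stop("d must be finite, in [0, pi]")
  if (max(d) <= 0)
    stop("all dissimilarities are zero: no differential-correlation signal")
  if (is.null(names(d))) stop("d must be named by gene ID")
  invisible(d)
}

#' @export
print.diss_weights <- function(x, ...) {
  cat(sprintf("%s weights over %d genes; d in [%.3f, %.3f]; %d excluded (d = 0)\n",
              x$type, length(x$d), min(x$d), max(x$d), sum(x$d == 0)))
  invisible(x)
}

#' Compute penalty weights from an expression matrix and annotation
#'
#' Convenience wrapper: per-class correlation matrices, angular
#' dissimilarity, then Twiner or iTwiner weights. By default correlations
#' are estimated on the provided samples only, so passing a training split
#' avoids test-set leakage.
#'
#' @param m Genes x samples matrix.
#' @param ann Annotation with classes.
#' @param sample_ids Samples to estimate correlations from (default: all
#'   annotated samples present in `m`).
#' @param type `"itwiner"` or `"twiner"`.
#' @param method Correlation method.
#' @param include_self Passed to [angular_dissimilarity()].
#' @return `diss_weights` object.
#' @export
compute_penalty_weights <- function(m, ann, sample_ids = NULL,
                                    type = c("itwiner", "twiner"),
                                    method = "pearson", include_self = TRUE) {
  type <- match.arg(type)
  ann <- validate_annotation(ann)
  if (is.null(sample_ids)) sample_ids <- intersect(colnames(m), ann$sample_id)
  cls <- ann$class[match(sample_ids, ann$sample_id)]
  sa <- group_correlation(m, sample_ids[cls == "P"], method = method)
  sb <- group_correlation(m, sample_ids[cls == "PM"], method = method)
  d <- angular_dissimilarity(sa, sb, include_self = include_self)
  if (type == "itwiner") itwiner_weights(d) else twiner_weights(d)
}

#' Write a weights table (gene, d, w, q) to CSV
#'
#' @param wts `diss_weights` object.
#' @param path Output CSV path.
#' @export
write_weights <- function(wts, path) {
  utils::write.csv(data.frame(gene_id = wts$gene_ids, d = wts$d, w = wts$w,
                              q = wts$q, row.names = NULL),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
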