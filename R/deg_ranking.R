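# Per-gene differential expression ranking with BH-FDR control.
#
# The per-gene test is a deliberate stand-in for a count-model DE pipeline:
# the downstream protocol only consumes a ranked gene list, so a Wilcoxon
# rank-sum test (default) or Welch t on the normalized log-scale matrix is
# used, followed by Benjamini-Hochberg adjustment.

#' Per-gene differential expression test between P and PM
#'
#' @param m Genes x samples expression matrix (normalized, log scale).
#' @param ann Annotation with `sample_id` and `class` covering the columns
#'   of `m` that should be used.
#' @param method `"rank_sum"` (Wilcoxon, default) or `"welch"`.
#' @param sample_ids Optional subset of samples to test (e.g. one balanced
#'   dataset, or a training split).
#' @return data.frame with `gene_id`, `log_fc` (mean log-expression in PM
#'   minus mean in P: positive = up-regulated in PM), `p_value`, `fdr`.
#' @export
de_test_per_gene <- function(m, ann, method = c("rank_sum", "welch"),
                             sample_ids = NULL) {
  method <- match.arg(method)
  validate_expression_matrix(m)
  ann <- validate_annotation(ann)
  if (is.null(sample_ids)) sample_ids <- intersect(colnames(m), ann$sample_id)
  cls <- ann$class[match(sample_ids, ann$sample_id)]
  if (anyNA(cls)) stop("sample IDs missing from annotation")
  p_ids <- sample_ids[cls == "P"]
  pm_ids <- sample_ids[cls == "PM"]
  if (length(p_ids) < 2L || length(pm_ids) < 2L)
    stop("both classes need at least 2 samples")
  xp <- m[, p_ids, drop = FALSE]
  xpm <- m[, pm_ids, drop = FALSE]
  log_fc <- rowMeans(xpm) - rowMeans(xp)
  pv <- vapply(seq_len(nrow(m)), function(i) {
    a <- xpm[i, ]; b <- xp[i, ]
    if (max(c(a, b)) == min(c(a, b))) return(1)  # fully tied gene
    if (method == "rank_sum") {
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    } else {
      if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
      stats::t.test(a, b)$p.value
    }
  }, numeric(1))
  pv[!is.finite(pv)] <- 1
  data.frame(gene_id = rownames(m), log_fc = log_fc, p_value = pv,
             fdr = bh_adjust(pv), row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Vector of raw p-values in (0, 1].
#' @return Adjusted values (monotone in p-value rank, clipped at 1).
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Top-k genes by p-value
#'
#' Optionally filters by an FDR cutoff, then takes the `k` smallest
#' p-values. Ties in p are broken by descending `|log_fc|`, then by gene ID,
#' so the output is deterministic.
#'
#' @param results data.frame from [de_test_per_gene()].
#' @param k Number of genes to keep.
#' @param fdr_cutoff Optional FDR threshold applied before ranking.
#' @return Character vector of gene IDs, ordered by increasing p-value. If
#'   fewer than `k` genes pass the cutoff, all passing genes are returned
#'   with a warning.
#' @export
top_k_by_pvalue <- function(results, k, fdr_cutoff = NULL) {
  if (k < 1L || k > nrow(results)) stop("k must be between 1 and the number of results")
  r <- results
  if (!is.null(fdr_cutoff)) r <- r[r$fdr <= fdr_cutoff, , drop = FALSE]
  ord <- order(r$p_value, -abs(r$log_fc), r$gene_id)
  r <- r[ord, , drop = FALSE]
  if (nrow(r) < k) {
    warning(sprintf("only %d genes pass the FDR cutoff (requested %d)", nrow(r), k))
    return(r$gene_id)
  }
  r$gene_id[seq_len(k)]
}

#' Venn-style overlap region counts for 2-3 gene sets
#'
#' @param sets Named list of 2 or 3 character vectors (no duplicates
#'   within a set).
#' @return Named integer vector of region counts, one per non-empty
#'   membership pattern; names join the member set names with `&`, genes
#'   exclusive to one set use that set's name alone. Region counts sum to
#'   the size of the union.
#' @export
overlap_counts <- function(sets) {
  if (length(sets) < 2L || length(sets) > 3L) stop("2 or 3 sets are required")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("S", seq_along(sets))
  sets <- lapply(sets, function(s) {
    if (anyDuplicated(s)) stop("duplicate gene IDs within a set")
    as.character(s)
  })
  univ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, names(sets)))
  pat <- apply(memb, 1L, function(row) paste(names(sets)[row], collapse = "&"))
  counts <- table(pat)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Write a DE result table in the conventional column layout
#'
#' @param results data.frame from [de_test_per_gene()].
#' @param path Output CSV path.
#' @export
write_de_results <- function(results, path) {
  out <- data.frame(gene_id = results$gene_id, logFC = results$log_fc,
                    PValue = results$p_value, FDR = results$fdr)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
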