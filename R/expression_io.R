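# Reading, validation, filtering and resampling of expression cohorts.

#' Read a gene x sample expression matrix from delimited text
#'
#' Reads a CSV or TSV file whose first column holds IDs and whose header row
#' holds the IDs of the other dimension. The canonical layout is genes as
#' rows and samples as columns; `orientation = "samples_rows"` transposes on
#' read so the returned matrix is always genes x samples.
#'
#' @param path Path to a delimited text file (`.csv` is comma-separated,
#'   anything else is read as tab-separated unless `sep` is given).
#' @param orientation `"genes_rows"` (default) or `"samples_rows"`.
#' @param sep Field separator; inferred from the file extension when `NULL`.
#' @return Numeric matrix (genes x samples) with gene IDs as rownames and
#'   sample IDs as colnames.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_rows", "samples_rows"),
                                   sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("expression file must have an ID column plus at least one data column")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated row IDs in ", path, ": ", paste(dup, collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      stop("non-numeric value in column '", colnames(body)[j], "', row '",
           ids[if (is.na(bad)) 1L else bad], "'")
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  validate_expression_matrix(m)
  message(sprintf("read expression matrix: %d genes x %d samples", nrow(m), ncol(m)))
  m
}

#' Write an expression matrix to delimited text
#'
#' @param m Genes x samples matrix with dimnames.
#' @param path Output path; `.csv` writes comma-separated, else tab.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the invariants assumed throughout the package: numeric matrix,
#' unique gene and sample IDs, all values finite.
#'
#' @param m Candidate matrix.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene IDs (rownames) and sample IDs (colnames)")
  if (anyDuplicated(rownames(m))) stop("duplicated gene IDs")
  if (anyDuplicated(colnames(m))) stop("duplicated sample IDs")
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(m)
}

#' Read a sample annotation table
#'
#' Requires columns `sample_id` and `class` (values `P`/`PM`). Optional
#' clinical columns (`sex`, `tissue`, `stage`, `sidedness`, `age`) and
#' survival columns (`surv_time`, `surv_event`) are kept when present.
#'
#' @param path CSV/TSV path.
#' @return data.frame keyed by `sample_id`.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ann <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' Validate a sample annotation table
#'
#' @param ann data.frame with at least `sample_id` and `class`.
#' @return The validated data.frame (class coerced to factor with levels
#'   `P`, `PM`).
#' @export
validate_annotation <- function(ann) {
  for (col in c("sample_id", "class")) {
    if (!col %in% names(ann)) stop("annotation is missing required column '", col, "'")
  }
  ann$sample_id <- as.character(ann$sample_id)
  if (anyDuplicated(ann$sample_id)) stop("duplicated sample_id in annotation")
  bad <- setdiff(unique(as.character(ann$class)), c("P", "PM"))
  if (length(bad)) stop("class labels must be 'P' or 'PM'; found: ", paste(bad, collapse = ", "))
  ann$class <- factor(as.character(ann$class), levels = c("P", "PM"))
  if ("surv_event" %in% names(ann) && !"surv_time" %in% names(ann))
    stop("surv_event present without surv_time")
  if ("surv_time" %in% names(ann)) {
    if (any(ann$surv_time < 0, na.rm = TRUE)) stop("surv_time must be nonnegative")
  }
  ann
}

#' Remove genes with constant expression
#'
#' Drops genes whose expression is identical across all samples (sample
#' standard deviation exactly zero); the relative order of the surviving
#' genes is preserved. Idempotent.
#'
#' @param m Genes x samples matrix.
#' @return Filtered matrix; the number of removed genes is reported via
#'   `message()`.
#' @export
filter_constant_genes <- function(m) {
  validate_expression_matrix(m)
  rng <- apply(m, 1L, function(x) max(x) - min(x))
  keep <- rng > 0   # exact: constant rows have max == min
  if (!any(keep)) stop("all genes are constant; empty feature space")
  message(sprintf("filter_constant_genes: removed %d of %d genes, %d remain",
                  sum(!keep), nrow(m), sum(keep)))
  m[keep, , drop = FALSE]
}

#' Log2 counts-per-million convenience transform
#'
#' `log2(CPM + 1)` from a raw count matrix; the package otherwise assumes a
#' user-supplied normalized log-scale matrix.
#'
#' @param counts Nonnegative genes x samples count matrix.
#' @return Matrix of `log2(1e6 * count / library_size + 1)`.
#' @export
normalize_log_cpm <- function(counts) {
  validate_expression_matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero library size")
  log2(sweep(counts, 2L, lib, "/") * 1e6 + 1)
}

#' Build class-balanced undersampled datasets
#'
#' Every partition contains all minority-class (PM) samples; majority-class
#' (P) samples are randomly divided across partitions without overlap, so
#' each partition is (approximately) class-balanced and the P cohort is used
#' in full across partitions.
#'
#' @param ann Annotation data.frame (`sample_id`, `class`).
#' @param n_partitions Number of balanced datasets to create.
#' @param sizes Optional integer vector of P-group sizes per partition
#'   (must sum to the number of P samples). Defaults to near-equal sizes
#'   (largest-remainder; sizes differ by at most 1).
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return Object of class `balanced_datasets`: list with `partitions`
#'   (list of sample-ID character vectors), `p_sizes`, `seed`.
#' @export
make_balanced_datasets <- function(ann, n_partitions = 3L, sizes = NULL, seed = 1L) {
  ann <- validate_annotation(ann)
  p_ids <- ann$sample_id[ann$class == "P"]
  pm_ids <- ann$sample_id[ann$class == "PM"]
  if (!length(p_ids) || !length(pm_ids)) stop("both classes must be non-empty")
  if (n_partitions < 1L) stop("n_partitions must be >= 1")
  if (n_partitions > length(p_ids))
    stop("n_partitions (", n_partitions, ") exceeds number of P samples (", length(p_ids), ")")
  if (is.null(sizes)) {
    base <- length(p_ids) %/% n_partitions
    rem <- length(p_ids) %% n_partitions
    sizes <- base + c(rep(1L, rem), rep(0L, n_partitions - rem))
  }
  if (length(sizes) != n_partitions || sum(sizes) != length(p_ids) || any(sizes < 1L))
    stop("sizes must be positive, one per partition, and sum to the number of P samples")
  set.seed(seed)
  perm <- sample(p_ids)
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  partitions <- lapply(seq_len(n_partitions), function(k) {
    sort(c(perm[starts[k]:stops[k]], pm_ids))
  })
  names(partitions) <- paste0("D", seq_len(n_partitions))
  structure(list(partitions = partitions, p_sizes = as.integer(sizes),
                 seed = as.integer(seed)),
            class = "balanced_datasets")
}

#' @export
print.balanced_datasets <- function(x, ...) {
  cat("balanced datasets:", length(x$partitions), "partitions\n")
  for (nm in names(x$partitions))
    cat(" ", nm, ": n =", length(x$partitions[[nm]]), "\n")
  invisible(x)
}

#' Stratified train/test split
#'
#' Allocates `round(fraction * n_class)` samples of each class to the
#' training set, the rest to the test set. Deterministic given the seed.
#'
#' @param sample_ids Character vector of sample IDs to split.
#' @param ann Annotation providing class labels for these IDs.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train_ids`, `test_ids`, `fraction`, `seed`.
#' @export
stratified_split <- function(sample_ids, ann, fraction = 0.7, seed = 1L) {
  ann <- validate_annotation(ann)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  cls <- ann$class[match(sample_ids, ann$sample_id)]
  if (anyNA(cls)) stop("sample IDs missing from annotation")
  set.seed(seed)
  train <- character(0)
  for (lev in levels(droplevels(cls))) {
    ids <- sample_ids[cls == lev]
    if (length(ids) < 2L) stop("class '", lev, "' has fewer than 2 samples")
    n_tr <- round(fraction * length(ids))
    n_tr <- max(1L, min(length(ids) - 1L, n_tr))
    train <- c(train, sample(ids, n_tr))
  }
  if (length(unique(cls)) < 2L) stop("both classes must be present")
  list(train_ids = sort(train),
       test_ids = sort(setdiff(sample_ids, train)),
       fraction = fraction, seed = as.integer(seed))
}

#' Encode class labels as the binary response
#'
#' P (non-metastatic) is the positive class and is coded 1; PM is coded 0.
#'
#' @param labels Character or factor vector of `P`/`PM` labels.
#' @return Integer 0/1 vector.
#' @export
encode_class <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("P", "PM"))
  if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "))
  as.integer(labels == "P")
}
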