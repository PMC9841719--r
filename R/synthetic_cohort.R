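# Synthetic two-class expression cohorts with planted structure.
#
# Three gene strata are planted: (1) a correlation block whose within-block
# pairwise correlation differs between classes but whose marginal mean and
# variance do not (the structure the angular-dissimilarity weights are
# built to detect, invisible to mean-based DE tests); (2) mean-shift genes,
# the classic DE signal; (3) null genes. Block genes follow a one-factor
# model per class, x_j = sqrt(rho) f + sqrt(1 - rho) eps, which gives
# exchangeable within-block correlation rho and unit marginal variance.
# Survival ties risk to class only (PM carries a higher hazard), making the
# log-rank contrast testable without gene-level survival effects.

#' Generate a synthetic two-class cohort
#'
#' Defaults reproduce the cohort used throughout the package's validation:
#' 60 samples per class, 200 genes, a 20-gene block with within-block
#' correlation 0.8 in P and 0 in PM, no mean-shift genes (pure
#' differential-correlation signal), unit noise.
#'
#' @param n_per_class Samples per class (P and PM).
#' @param p_genes Total genes.
#' @param block_size Size of the differential-correlation block.
#' @param rho_p,rho_pm Within-block correlation in class P / PM, in `[0, 1)`.
#' @param n_shift_genes Genes with a mean shift between classes.
#' @param shift Shift added to the PM mean of shift genes (log-units).
#' @param noise_sd Marginal standard deviation of every gene.
#' @param base_hazard Exponential event rate for class P (per month).
#' @param hazard_ratio_pm Multiplier on the PM hazard.
#' @param censor_time Administrative censoring horizon (uniform entry).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Object of class `synthetic_cohort`: `expression` (genes x
#'   samples), `annotation` (sample_id, class, sex, tissue, stage,
#'   sidedness, age, surv_time, surv_event), `truth` (list of gene-ID
#'   vectors `corr_block`, `shift`, `null` partitioning the genome) and the
#'   configuration.
#' @export
generate_cohort <- function(n_per_class = 60L, p_genes = 200L, block_size = 20L,
                            rho_p = 0.8, rho_pm = 0, n_shift_genes = 0L,
                            shift = 2, noise_sd = 1, base_hazard = 1 / 60,
                            hazard_ratio_pm = 3, censor_time = 120, seed = 1L) {
  if (rho_p < 0 || rho_p >= 1 || rho_pm < 0 || rho_pm >= 1)
    stop("rho must be in [0, 1)")
  if (block_size + n_shift_genes > p_genes)
    stop("block_size + n_shift_genes exceeds p_genes")
  if (n_per_class < 2L) stop("n_per_class must be >= 2")
  if (!is.finite(shift)) stop("shift must be finite")
  set.seed(seed)

  gene_ids <- sprintf("g%04d", seq_len(p_genes))
  block <- gene_ids[seq_len(block_size)]
  shift_genes <- if (n_shift_genes > 0)
    gene_ids[block_size + seq_len(n_shift_genes)] else character(0)
  nulls <- setdiff(gene_ids, c(block, shift_genes))

  sim_class <- function(n, rho) {
    x <- matrix(stats::rnorm(p_genes * n), nrow = p_genes)
    if (block_size > 0L) {
      f <- stats::rnorm(n)
      x[seq_len(block_size), ] <-
        sqrt(rho) * matrix(f, block_size, n, byrow = TRUE) +
        sqrt(1 - rho) * x[seq_len(block_size), , drop = FALSE]
    }
    x * noise_sd
  }
  xp <- sim_class(n_per_class, rho_p)
  xpm <- sim_class(n_per_class, rho_pm)
  if (length(shift_genes))
    xpm[match(shift_genes, gene_ids), ] <-
      xpm[match(shift_genes, gene_ids), , drop = FALSE] + shift

  expr <- cbind(xp, xpm)
  rownames(expr) <- gene_ids
  colnames(expr) <- c(sprintf("P_%03d", seq_len(n_per_class)),
                      sprintf("PM_%03d", seq_len(n_per_class)))
  cls <- rep(c("P", "PM"), each = n_per_class)
  n <- 2L * n_per_class

  haz <- base_hazard * ifelse(cls == "PM", hazard_ratio_pm, 1)
  t_event <- stats::rexp(n, rate = haz)
  t_cens <- stats::runif(n, 0, censor_time)
  ann <- data.frame(
    sample_id = colnames(expr),
    class = cls,
    sex = sample(c("Female", "Male"), n, replace = TRUE),
    tissue = sample(c("Colon", "Rectum"), n, replace = TRUE, prob = c(0.85, 0.15)),
    stage = ifelse(cls == "P",
                   sample(c("II", "III"), n, replace = TRUE, prob = c(0.7, 0.3)),
                   sample(c("II", "III"), n, replace = TRUE, prob = c(1 / 3, 2 / 3))),
    sidedness = sample(c("Right", "Left"), n, replace = TRUE),
    age = round(stats::rnorm(n, mean = 68.5, sd = 8), 1),
    surv_time = pmin(t_event, t_cens),
    surv_event = t_event <= t_cens,
    stringsAsFactors = FALSE)

  structure(list(expression = expr, annotation = ann,
                 truth = list(corr_block = block, shift = shift_genes,
                              null = nulls),
                 config = list(n_per_class = n_per_class, p_genes = p_genes,
                               block_size = block_size, rho_p = rho_p,
                               rho_pm = rho_pm, n_shift_genes = n_shift_genes,
                               shift = shift, noise_sd = noise_sd,
                               base_hazard = base_hazard,
                               hazard_ratio_pm = hazard_ratio_pm,
                               censor_time = censor_time, seed = seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("synthetic cohort: %d genes x %d samples (%d/class); block %d (rho %g vs %g), %d shift genes\n",
              nrow(x$expression), ncol(x$expression), cfg$n_per_class,
              cfg$block_size, cfg$rho_p, cfg$rho_pm, cfg$n_shift_genes))
  invisible(x)
}

#' Precision and recall of a selected gene set against the planted truth
#'
#' @param selected Character vector of selected gene IDs.
#' @param truth Truth list from [generate_cohort()].
#' @param target `"corr_block"` or `"shift"`.
#' @return List with `precision` (`NA` when nothing was selected) and
#'   `recall`.
#' @export
evaluate_recovery <- function(selected, truth, target = c("corr_block", "shift")) {
  target <- match.arg(target)
  ts <- truth[[target]]
  if (!length(ts)) stop("truth set '", target, "' is empty")
  hits <- length(intersect(selected, ts))
  list(precision = if (length(selected)) hits / length(selected) else NA_real_,
       recall = hits / length(ts))
}

#' Write a synthetic cohort to disk
#'
#' Writes the expression CSV and annotation CSV in the layout consumed by
#' [read_expression_matrix()] / [read_sample_annotation()], plus a truth
#' JSON.
#'
#' @param cohort `synthetic_cohort` object.
#' @param dir Output directory (created if missing).
#' @return Named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.csv"),
             annotation = file.path(dir, "annotation.csv"),
             truth = file.path(dir, "truth.json"))
  write_expression_matrix(cohort$expression, paths[["expression"]])
  utils::write.csv(cohort$annotation, paths[["annotation"]], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]])
  paths
}
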