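# Group-comparison and survival statistics for the clinical covariates.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value from the exact hypergeometric distribution with fixed
#' margins, summing the probabilities of all tables at most as probable as
#' the observed one (the minimum-likelihood convention of
#' [stats::fisher.test()]).
#'
#' @param tab 2x2 matrix of nonnegative counts (rows = class P/PM,
#'   columns = factor levels).
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0)) stop("table entries must be nonnegative")
  if (sum(tab) == 0) stop("table has no observations")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Welch two-sample t-test p-value
#'
#' Two-sided p-value for a difference in means; unequal variances
#' (Welch-Satterthwaite degrees of freedom) by default, pooled-variance
#' Student t behind `var_equal = TRUE`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param var_equal Assume equal variances (classic two-sample t).
#' @return Two-sided p-value.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs at least 2 samples")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("both groups have zero variance")
  stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided")$p.value
}

#' Two-group log-rank test
#'
#' Unweighted log-rank test comparing survival between two groups; the
#' statistic is referred to a chi-square distribution with 1 degree of
#' freedom. Ties are handled through the hypergeometric variance.
#'
#' @param time Nonnegative follow-up times.
#' @param event Logical/0-1 event indicator (TRUE = event observed).
#' @param group Two-level grouping vector.
#' @return List with `chi_square` and `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and nonnegative")
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) != 2L) stop("exactly two non-empty groups are required")
  event <- as.logical(event)
  if (!any(event)) stop("at least one event is required")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(fit$chisq)
  list(chi_square = chisq,
       p_value = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Nonnegative follow-up times.
#' @param event Logical/0-1 event indicator.
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `surv`;
#'   a leading row at time 0 with `surv = 1` makes the step function
#'   explicit. The estimate is monotone non-increasing in `[0, 1]`.
#' @export
kaplan_meier_curve <- function(time, event) {
  if (length(time) < 1L) stop("at least one sample is required")
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and nonnegative")
  event <- as.logical(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event),
             surv = c(1, fit$surv))
}

#' Clinical summary table across balanced datasets
#'
#' For each categorical covariate present in the annotation (`sex`,
#' `tissue`, `stage`, `sidedness`) the per-class level counts and the
#' Fisher exact p-value comparing P vs PM are computed per dataset; `age`
#' is compared by a Welch t-test on the means.
#'
#' @param ann Annotation data.frame.
#' @param datasets `balanced_datasets` object (or named list of sample-ID
#'   vectors).
#' @return Long data.frame: dataset, factor, level (or "mean" for age),
#'   count/mean in P and PM, p_value (repeated across levels of a factor).
#' @export
clinical_summary_table <- function(ann, datasets) {
  ann <- validate_annotation(ann)
  parts <- if (inherits(datasets, "balanced_datasets")) datasets$partitions else datasets
  out <- list()
  for (dn in names(parts)) {
    sub <- ann[ann$sample_id %in% parts[[dn]], , drop = FALSE]
    for (fac in intersect(c("sex", "tissue", "stage", "sidedness"), names(sub))) {
      tb <- table(sub$class, as.character(sub[[fac]]))
      p <- if (ncol(tb) == 2L) fisher_exact_two_sided(t(tb)) else NA_real_
      for (lev in colnames(tb)) {
        out[[length(out) + 1L]] <- data.frame(
          dataset = dn, factor = fac, level = lev,
          P = tb["P", lev], PM = tb["PM", lev], p_value = p,
          stringsAsFactors = FALSE)
      }
    }
    if ("age" %in% names(sub)) {
      p <- welch_t_test(sub$age[sub$class == "P"], sub$age[sub$class == "PM"])
      out[[length(out) + 1L]] <- data.frame(
        dataset = dn, factor = "age", level = "mean",
        P = mean(sub$age[sub$class == "P"]),
        PM = mean(sub$age[sub$class == "PM"]), p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
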