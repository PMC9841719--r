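# Classifier benchmark: five reference classifiers evaluated over resampled
# stratified 70/30 splits, with features drawn from DEG ranking or from the
# genes selected by (weighted) elastic-net logistic regression.

#' Confusion counts and derived metrics
#'
#' P (non-metastatic) is the positive class. TP = true P predicted P,
#' FN = true P predicted PM, TN = true PM predicted PM, FP = true PM
#' predicted P. AUC is the rank-based probability that a random P sample
#' scores above a random PM sample (mid-ranks for ties).
#'
#' @param y_true,y_pred Vectors of `P`/`PM` labels, equal length.
#' @param scores Numeric scores, higher = more P-like (e.g. predicted P
#'   probability).
#' @return List: `tp`, `fp`, `tn`, `fn`, `accuracy`, `miscl`,
#'   `sensitivity`, `specificity`, `auc`.
#' @export
confusion_metrics <- function(y_true, y_pred, scores) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) != length(scores))
    stop("y_true, y_pred and scores must have equal length")
  if (!all(c(y_true, y_pred) %in% c("P", "PM"))) stop("labels must be 'P' or 'PM'")
  if (length(unique(y_true)) < 2L)
    stop("test truth contains a single class; AUC undefined")
  tp <- sum(y_true == "P" & y_pred == "P")
  fn <- sum(y_true == "P" & y_pred == "PM")
  tn <- sum(y_true == "PM" & y_pred == "PM")
  fp <- sum(y_true == "PM" & y_pred == "P")
  n_p <- tp + fn; n_pm <- tn + fp
  r <- rank(scores)
  auc <- (sum(r[y_true == "P"]) - n_p * (n_p + 1) / 2) / (n_p * n_pm)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y_true),
       miscl = fp + fn,
       sensitivity = tp / n_p,
       specificity = tn / n_pm,
       auc = auc)
}

# stratified fold ids for internal hyper-parameter tuning
.fold_ids <- function(y, n_folds) {
  foldid <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

# generic grid search by stratified-CV accuracy; returns index of best row
.cv_tune <- function(X, y, grid, fit_fun, pred_fun, n_folds = 10L) {
  n_folds <- min(n_folds, min(table(y)))
  foldid <- .fold_ids(y, n_folds)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ok <- 0L
    for (k in seq_len(n_folds)) {
      tr <- foldid != k
      fit <- fit_fun(grid[g, , drop = FALSE], X[tr, , drop = FALSE], y[tr])
      pr <- pred_fun(fit, X[!tr, , drop = FALSE])
      ok <- ok + sum(pr == y[!tr])
    }
    acc[g] <- ok / length(y)
  }
  which.max(acc)
}

#' Train one of the five benchmark classifiers
#'
#' `DT` is an rpart tree with `minsplit = 4`, `minbucket = floor(4/3)` and
#' the maximum depth tuned by stratified 10-fold CV; `svmL`/`svmR` are
#' e1071 SVMs with cost (and, for the radial kernel, gamma) tuned the same
#' way; `LR` is an unpenalized logistic GLM; `RF` is a 500-tree random
#' forest with `mtry` chosen by out-of-bag error. Deterministic under the
#' seed.
#'
#' @param X Samples x features numeric matrix.
#' @param y `P`/`PM` labels (any coercible vector).
#' @param method One of `"DT"`, `"svmL"`, `"svmR"`, `"LR"`, `"RF"`.
#' @param seed Integer seed.
#' @param n_folds CV folds for tuning.
#' @return Object of class `bench_classifier`; predict with
#'   [predict_classifier()].
#' @export
train_classifier <- function(X, y, method = c("DT", "svmL", "svmR", "LR", "RF"),
                             seed = 1L, n_folds = 10L) {
  method <- match.arg(method)
  y <- factor(as.character(y), levels = c("PM", "P"))
  if (any(is.na(y))) stop("labels must be 'P' or 'PM'")
  if (nlevels(droplevels(y)) < 2L) stop("training set must contain both classes")
  if (!is.matrix(X) || nrow(X) != length(y)) stop("X must be a samples x features matrix matching y")
  set.seed(seed)
  p <- ncol(X)
  df <- data.frame(y = y, X, check.names = FALSE)

  fit <- tuning <- NULL
  if (method == "DT") {
    grid <- data.frame(maxdepth = 1:8)
    ctrl <- function(d) rpart::rpart.control(minsplit = 4L, minbucket = 1L,
                                             maxdepth = d, cp = 1e-4, xval = 0L)
    best <- .cv_tune(X, y, grid,
                     fit_fun = function(g, Xtr, ytr)
                       rpart::rpart(y ~ ., data = data.frame(y = ytr, Xtr, check.names = FALSE),
                                    method = "class", control = ctrl(g$maxdepth)),
                     pred_fun = function(f, Xte)
                       predict(f, data.frame(Xte, check.names = FALSE), type = "class"),
                     n_folds = n_folds)
    tuning <- grid[best, , drop = FALSE]
    fit <- rpart::rpart(y ~ ., data = df, method = "class",
                        control = ctrl(tuning$maxdepth))
  } else if (method %in% c("svmL", "svmR")) {
    kern <- if (method == "svmL") "linear" else "radial"
    grid <- if (method == "svmL") {
      data.frame(cost = c(0.25, 1, 4))
    } else {
      expand.grid(cost = c(0.25, 1, 4), gamma = (1 / p) * c(0.5, 1, 2))
    }
    sfit <- function(g, Xtr, ytr) {
      args <- list(x = Xtr, y = ytr, kernel = kern, cost = g$cost,
                   probability = TRUE, scale = FALSE)
      if (kern == "radial") args$gamma <- g$gamma
      do.call(e1071::svm, args)
    }
    best <- .cv_tune(X, y, grid, fit_fun = sfit,
                     pred_fun = function(f, Xte) predict(f, Xte),
                     n_folds = n_folds)
    tuning <- grid[best, , drop = FALSE]
    fit <- sfit(tuning, X, y)
  } else if (method == "LR") {
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  } else { # RF
    mtry_grid <- sort(unique(pmax(1L, pmin(p, c(floor(sqrt(p) / 2), floor(sqrt(p)),
                                                2L * floor(sqrt(p)))))))
    oob <- vapply(mtry_grid, function(m) {
      f <- randomForest::randomForest(x = X, y = y, ntree = 250L, mtry = m)
      f$err.rate[f$ntree, "OOB"]
    }, numeric(1))
    tuning <- data.frame(mtry = mtry_grid[which.min(oob)])
    fit <- randomForest::randomForest(x = X, y = y, ntree = 500L, mtry = tuning$mtry)
  }
  structure(list(method = method, fit = fit, tuning = tuning,
                 features = colnames(X), seed = as.integer(seed)),
            class = "bench_classifier")
}

#' Predict with a benchmark classifier
#'
#' @param object `bench_classifier` from [train_classifier()].
#' @param X_new Samples x features matrix with the training features.
#' @return List: `class` (character `P`/`PM`) and `score` (probability of
#'   P, or the closest analogue the classifier offers).
#' @export
predict_classifier <- function(object, X_new) {
  if (!inherits(object, "bench_classifier")) stop("object must be a bench_classifier")
  if (!is.null(colnames(X_new)) && !is.null(object$features))
    X_new <- X_new[, object$features, drop = FALSE]
  m <- object$method
  if (m == "DT") {
    pr <- predict(object$fit, data.frame(X_new, check.names = FALSE), type = "prob")[, "P"]
  } else if (m %in% c("svmL", "svmR")) {
    pred <- predict(object$fit, X_new, probability = TRUE)
    pr <- attr(pred, "probabilities")[, "P"]
  } else if (m == "LR") {
    pr <- suppressWarnings(
      stats::predict(object$fit, data.frame(X_new, check.names = FALSE),
                     type = "response"))  # P is the second factor level
  } else {
    pr <- predict(object$fit, X_new, type = "prob")[, "P"]
  }
  pr <- as.numeric(pr)
  list(class = ifelse(pr > 0.5, "P", "PM"), score = pr)
}

# per-run feature selection on the training portion
.run_features <- function(m, ann, train_ids, feature_source, n_top, alpha,
                          seed, de_method) {
  Xtr <- t(m[, train_ids, drop = FALSE])
  ytr <- encode_class(ann$class[match(train_ids, ann$sample_id)])
  if (feature_source == "deg_top50") {
    de <- de_test_per_gene(m, ann, method = de_method, sample_ids = train_ids)
    list(features = top_k_by_pvalue(de, min(n_top, nrow(de))), model = NULL)
  } else {
    q <- NULL
    if (feature_source %in% c("itwiner_top50", "full_regularized_itwiner")) {
      wts <- compute_penalty_weights(m, ann, sample_ids = train_ids, type = "itwiner")
      q <- wts$penalty
    }
    a <- if (!is.null(alpha)) alpha else if (is.null(q)) 0.2 else 0.05
    fit <- itwiner_fit(Xtr, ytr, alpha = a, q = q, seed = seed)
    sel <- selected_genes(fit)
    if (is.finite(n_top) && length(sel) < n_top) {
      # top up by entry order along the regularization path so the
      # feature set always reaches the protocol's fixed size
      rank_all <- path_gene_ranking(Xtr, ytr, alpha = a, q = q)
      sel <- c(sel, setdiff(rank_all, sel))
    }
    list(features = utils::head(sel, n_top), model = fit)
  }
}

#' Run the resampled classification benchmark
#'
#' Per run: a stratified 70/30 split; the feature set is computed from the
#' training portion (DEG top-k, or top-k by `|coefficient|` from a
#' cross-validated (weighted) elastic-net fit on the training data);
#' classifiers are trained on the training portion and scored on the test
#' portion. `feature_source = "full_regularized"` skips the downstream
#' classifiers and evaluates the regularized logistic model itself (0.5
#' probability threshold), feeding each run's selected genes into the
#' selection profile. With `paper_mode = TRUE` the feature list is computed
#' once on the full dataset before the runs (the workflow that fixed
#' 50-gene tables imply), at the cost of information leaking from test
#' splits into feature selection.
#'
#' @param m Genes x samples expression matrix.
#' @param ann Annotation.
#' @param sample_ids Samples forming the (balanced) dataset; default all
#'   annotated columns of `m`.
#' @param feature_source One of `"deg_top50"`, `"en_top50"`,
#'   `"itwiner_top50"`, `"full_regularized"`.
#' @param regularizer For `"full_regularized"`: `"en"` or `"itwiner"`.
#' @param classifiers Subset of `c("DT","svmL","svmR","LR","RF")`.
#' @param n_runs Number of resampled splits.
#' @param seed Master seed; run r uses `seed + r`.
#' @param n_top Feature-set size (50 in the reference protocol).
#' @param fraction Training fraction.
#' @param alpha Elastic-net mixing parameter; defaults to 0.2 for the plain
#'   elastic net and 0.05 for iTwiner.
#' @param de_method Per-gene DE test for `"deg_top50"`.
#' @param paper_mode Compute the feature list once on the full dataset.
#' @return Object of class `benchmark_result`: `summary` (median and SD of
#'   each metric per classifier), `runs` (per-run long data.frame),
#'   `selection_profile` (for `"full_regularized"`), `config`.
#' @export
run_benchmark <- function(m, ann, sample_ids = NULL,
                          feature_source = c("deg_top50", "en_top50",
                                             "itwiner_top50", "full_regularized"),
                          regularizer = c("itwiner", "en"),
                          classifiers = c("DT", "svmL", "svmR", "LR", "RF"),
                          n_runs = 100L, seed = 1L, n_top = 50L,
                          fraction = 0.7, alpha = NULL,
                          de_method = "rank_sum", paper_mode = FALSE) {
  feature_source <- match.arg(feature_source)
  regularizer <- match.arg(regularizer)
  ann <- validate_annotation(ann)
  validate_expression_matrix(m)
  if (is.null(sample_ids)) sample_ids <- intersect(colnames(m), ann$sample_id)
  src <- if (feature_source == "full_regularized")
    paste0("full_regularized_", regularizer) else feature_source

  fixed <- NULL
  if (paper_mode && feature_source != "full_regularized")
    fixed <- .run_features(m, ann, sample_ids, src, n_top, alpha, seed, de_method)

  rows <- list()
  sel_sets <- list()
  for (r in seq_len(n_runs)) {
    rs <- seed + r
    sp <- stratified_split(sample_ids, ann, fraction = fraction, seed = rs)
    te_cls <- as.character(ann$class[match(sp$test_ids, ann$sample_id)])
    if (length(unique(te_cls)) < 2L)
      stop("run ", r, ": test set contains a single class")
    if (feature_source == "full_regularized") {
      fs <- .run_features(m, ann, sp$train_ids, src, Inf, alpha, rs, de_method)
      sel_sets[[r]] <- selected_genes(fs$model)
      pr <- predict_probability(fs$model, t(m[, sp$test_ids, drop = FALSE]))
      met <- confusion_metrics(te_cls, ifelse(pr > 0.5, "P", "PM"), pr)
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, classifier = regularizer, n_genes = length(sel_sets[[r]]),
        as.data.frame(met), stringsAsFactors = FALSE)
    } else {
      fs <- if (paper_mode) fixed else
        .run_features(m, ann, sp$train_ids, src, n_top, alpha, rs, de_method)
      feats <- fs$features
      if (length(feats) < 2L) stop("run ", r, ": fewer than 2 features selected")
      Xtr <- t(m[feats, sp$train_ids, drop = FALSE])
      Xte <- t(m[feats, sp$test_ids, drop = FALSE])
      ytr <- as.character(ann$class[match(sp$train_ids, ann$sample_id)])
      for (cl in classifiers) {
        clf <- train_classifier(Xtr, ytr, method = cl, seed = rs)
        pred <- predict_classifier(clf, Xte)
        met <- confusion_metrics(te_cls, pred$class, pred$score)
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, classifier = cl, n_genes = length(feats),
          as.data.frame(met), stringsAsFactors = FALSE)
      }
    }
  }
  runs <- do.call(rbind, rows)
  metrics <- c("accuracy", "miscl", "fn", "sensitivity", "specificity", "auc", "n_genes")
  summ <- do.call(rbind, lapply(split(runs, runs$classifier), function(d) {
    out <- data.frame(classifier = d$classifier[1L], n_runs = nrow(d))
    for (mt in metrics) {
      out[[paste0(mt, "_median")]] <- stats::median(d[[mt]])
      out[[paste0(mt, "_sd")]] <- stats::sd(d[[mt]])
    }
    out
  }))
  rownames(summ) <- NULL
  prof <- if (length(sel_sets)) selection_frequency(sel_sets) else NULL
  structure(list(summary = summ, runs = runs, selection_profile = prof,
                 config = list(feature_source = feature_source,
                               regularizer = regularizer, n_runs = n_runs,
                               seed = seed, n_top = n_top, fraction = fraction,
                               alpha = alpha, paper_mode = paper_mode,
                               de_method = de_method,
                               classifiers = classifiers)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark:", x$config$feature_source, "over", x$config$n_runs, "runs\n")
  print(x$summary[, c("classifier", "accuracy_median", "accuracy_sd", "auc_median")])
  invisible(x)
}

#' Pairwise Wilcoxon comparison of per-run accuracies
#'
#' Two-sided rank-sum p-value for every pair of methods, BH-adjusted across
#' the pairs. Identical constant vectors compare with p = 1.
#'
#' @param acc_list Named list of equal-length numeric accuracy vectors.
#' @return Symmetric matrix of adjusted p-values (diagonal 1).
#' @export
compare_accuracies_pairwise <- function(acc_list) {
  k <- length(acc_list)
  if (k < 2L) stop("at least two methods are required")
  if (length(unique(lengths(acc_list))) != 1L) stop("equal run counts are required")
  nms <- names(acc_list)
  pairs <- utils::combn(k, 2L)
  raw <- apply(pairs, 2L, function(ij) {
    a <- acc_list[[ij[1L]]]; b <- acc_list[[ij[2L]]]
    if (max(c(a, b)) == min(c(a, b))) return(1)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  })
  adj <- stats::p.adjust(raw, method = "BH")
  out <- matrix(1, k, k, dimnames = list(nms, nms))
  for (j in seq_len(ncol(pairs))) {
    out[pairs[1L, j], pairs[2L, j]] <- adj[j]
    out[pairs[2L, j], pairs[1L, j]] <- adj[j]
  }
  out
}

#' Gene selection frequency across runs
#'
#' @param sets List of per-run selected gene-ID vectors.
#' @param n_runs Total run count (default `length(sets)`).
#' @param threshold Fraction of runs defining the "commonly selected" set
#'   (default 0.5: selected in at least 50% of runs).
#' @return Object of class `selection_profile`: `counts` (named integer
#'   vector, decreasing, ties broken by gene ID), `threshold_set`,
#'   `n_runs`, `threshold`.
#' @export
selection_frequency <- function(sets, n_runs = length(sets), threshold = 0.5) {
  if (!length(sets)) stop("at least one run is required")
  genes <- unlist(sets)
  if (!length(genes)) {
    counts <- integer(0)
  } else {
    tb <- table(genes)
    counts <- as.integer(tb)
    names(counts) <- names(tb)
    counts <- counts[order(-counts, names(counts))]
  }
  structure(list(counts = counts,
                 threshold_set = names(counts)[counts >= threshold * n_runs],
                 n_runs = n_runs, threshold = threshold),
            class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf("selection profile over %d runs: %d genes ever selected, %d in >= %d%% of runs\n",
              x$n_runs, length(x$counts), length(x$threshold_set),
              round(100 * x$threshold)))
  invisible(x)
}
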