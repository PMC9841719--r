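test_that("confusion-metric identities hold on enumerated tables", {
  make_case <- function(tp, fn, tn, fp) {
    y_true <- c(rep("P", tp + fn), rep("PM", tn + fp))
    y_pred <- c(rep("P", tp), rep("PM", fn), rep("PM", tn), rep("P", fp))
    scores <- ifelse(y_pred == "P", 0.9, 0.1)
    confusion_metrics(y_true, y_pred, scores)
  }
  for (tp in 0:3) for (fn in 0:3) for (tn in 1:3) for (fp in 0:3) {
    if (tp + fn == 0) next
    m <- make_case(tp, fn, tn, fp)
    total <- tp + fn + tn + fp
    expect_identical(m$tp + m$fp + m$tn + m$fn, total)
    expect_equal(m$accuracy, (tp + tn) / total)
    expect_equal(m$miscl, fp + fn)
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
  }

  # the worked 18-sample example: tp=7, fn=2, tn=6, fp=3
  m <- make_case(7, 2, 6, 3)
  expect_equal(m$accuracy, 13 / 18)
  expect_equal(m$sensitivity, 7 / 9)
  expect_equal(m$specificity, 6 / 9)

  # perfect prediction on a 9+9 test set
  mp <- make_case(9, 0, 9, 0)
  expect_equal(mp$accuracy, 1)
  expect_identical(mp$miscl, 0L)
  expect_equal(mp$auc, 1)

  # inverting every prediction complements the accuracy
  y_true <- rep(c("P", "PM"), c(5, 7))
  y_pred <- c(rep("P", 3), rep("PM", 2), rep("PM", 4), rep("P", 3))
  sc <- ifelse(y_pred == "P", 0.8, 0.2)
  inv <- ifelse(y_pred == "P", "PM", "P")
  a1 <- confusion_metrics(y_true, y_pred, sc)$accuracy
  a2 <- confusion_metrics(y_true, inv, 1 - sc)$accuracy
  expect_equal(a2, 1 - a1)

  expect_error(confusion_metrics(rep("P", 4), rep("P", 4), runif(4)),
               "single class")
})

test_that("AUC is antisymmetric under score negation and uses mid-ranks", {
  set.seed(12)
  y <- rep(c("P", "PM"), each = 10)
  s <- c(rnorm(10, 1), rnorm(10))
  pred <- ifelse(s > 0.5, "P", "PM")
  a <- confusion_metrics(y, pred, s)$auc
  a_neg <- confusion_metrics(y, pred, -s)$auc
  expect_equal(a + a_neg, 1)
  # ties handled by mid-ranks: all-equal scores give AUC 0.5
  expect_equal(confusion_metrics(y, pred, rep(1, 20))$auc, 0.5)
})

test_that("every classifier separates a linearly separable toy set and is seed-stable", {
  set.seed(4)
  n <- 15
  X <- rbind(matrix(rnorm(n * 2, mean = 3, sd = 0.3), n, 2),
             matrix(rnorm(n * 2, mean = -3, sd = 0.3), n, 2))
  colnames(X) <- c("gene1", "gene2")
  y <- rep(c("P", "PM"), each = n)
  for (cl in c("DT", "svmL", "svmR", "LR", "RF")) {
    clf <- train_classifier(X, y, method = cl, seed = 8)
    pred <- predict_classifier(clf, X)
    expect_equal(mean(pred$class == y), 1, info = cl)
  }
  # determinism: same data + seed gives identical predictions
  set.seed(77); Xn <- X + matrix(rnorm(length(X), sd = 2), nrow(X))
  f1 <- train_classifier(Xn, y, method = "RF", seed = 5)
  f2 <- train_classifier(Xn, y, method = "RF", seed = 5)
  expect_identical(predict_classifier(f1, Xn)$score,
                   predict_classifier(f2, Xn)$score)
})

test_that("label-permuted data yields chance-level accuracy", {
  set.seed(60)
  n <- 40; p <- 10
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  y <- rep(c("P", "PM"), each = n / 2)
  ann <- make_ann(paste0("s", 1:n), y)
  rownames(X) <- ann$sample_id
  accs <- vapply(1:20, function(r) {
    yp <- sample(y)   # permuted labels: no signal
    sp <- stratified_split(ann$sample_id, make_ann(ann$sample_id, yp), 0.7,
                           seed = r)
    tr <- match(sp$train_ids, ann$sample_id)
    te <- match(sp$test_ids, ann$sample_id)
    clf <- train_classifier(X[tr, ], yp[tr], method = "DT", seed = r)
    pred <- predict_classifier(clf, X[te, ])
    mean(pred$class == yp[te])
  }, numeric(1))
  expect_lt(abs(median(accs) - 0.5), 0.15)
})

test_that("pairwise accuracy comparison adjusts with BH and handles degenerate input", {
  same <- rep(0.7, 30)
  out <- compare_accuracies_pairwise(list(a = same, b = same))
  expect_equal(out["a", "b"], 1)
  expect_equal(diag(out), c(a = 1, b = 1))

  set.seed(2)
  lo <- runif(100, 0.4, 0.5); hi <- runif(100, 0.8, 0.9); mid <- runif(100, 0.55, 0.75)
  m3 <- compare_accuracies_pairwise(list(lo = lo, mid = mid, hi = hi))
  expect_lt(m3["lo", "hi"], 0.001)
  expect_true(isSymmetric(m3))

  # BH never lowers the smallest raw p
  raw <- suppressWarnings(stats::wilcox.test(lo, hi)$p.value)
  expect_gte(m3["lo", "hi"], raw)

  expect_error(compare_accuracies_pairwise(list(a = 1:3)), "two methods")
  expect_error(compare_accuracies_pairwise(list(a = 1:3, b = 1:4)), "equal run counts")
})

test_that("selection frequency counts runs, applies the 50% threshold, and breaks ties by ID", {
  sets <- c(replicate(60, "gKeep", simplify = FALSE),
            replicate(40, character(0), simplify = FALSE))
  sets <- Map(c, sets, c(replicate(49, "gDrop", simplify = FALSE),
                         replicate(51, character(0), simplify = FALSE)))
  prof <- selection_frequency(sets, n_runs = 100)
  expect_identical(unname(prof$counts["gKeep"]), 60L)
  expect_true("gKeep" %in% prof$threshold_set)
  expect_identical(unname(prof$counts["gDrop"]), 49L)
  expect_false("gDrop" %in% prof$threshold_set)

  empty <- selection_frequency(replicate(5, character(0), simplify = FALSE))
  expect_length(empty$counts, 0)
  expect_length(empty$threshold_set, 0)

  tied <- selection_frequency(list(c("gB", "gA"), c("gA", "gB")))
  expect_identical(names(tied$counts), c("gA", "gB"))
})

test_that("a single-run benchmark reduces to one split evaluation and reproduces exactly", {
  co <- tiny_cohort(seed = 10, n_per_class = 15, p_genes = 30, block_size = 6)
  br <- run_benchmark(co$expression, co$annotation, feature_source = "deg_top50",
                      classifiers = "DT", n_runs = 1, seed = 2, n_top = 10)
  expect_identical(nrow(br$runs), 1L)
  expect_identical(br$summary$n_runs, 1L)
  expect_equal(br$summary$accuracy_median, br$runs$accuracy)
  br2 <- run_benchmark(co$expression, co$annotation, feature_source = "deg_top50",
                       classifiers = "DT", n_runs = 1, seed = 2, n_top = 10)
  expect_identical(br$runs, br2$runs)
})

test_that("full-regularized benchmark evaluates the penalized model and profiles selections", {
  co <- tiny_cohort(seed = 14, n_per_class = 15, p_genes = 30, block_size = 0,
                    n_shift_genes = 6, shift = 2.5)
  br <- run_benchmark(co$expression, co$annotation,
                      feature_source = "full_regularized", regularizer = "en",
                      n_runs = 3, seed = 6)
  expect_identical(nrow(br$runs), 3L)
  expect_s3_class(br$selection_profile, "selection_profile")
  expect_true(all(br$selection_profile$counts <= 3))
  # strong mean-shift signal: the penalized model classifies well
  expect_gt(median(br$runs$accuracy), 0.7)
})

test_that("planted genes are selected more often under iTwiner than under the elastic net", {
  co <- generate_cohort(seed = 99)   # pure differential-correlation cohort
  counts_for <- function(reg) {
    br <- run_benchmark(co$expression, co$annotation,
                        feature_source = "full_regularized", regularizer = reg,
                        n_runs = 25, seed = 7)
    full <- setNames(rep(0L, nrow(co$expression)), rownames(co$expression))
    full[names(br$selection_profile$counts)] <- br$selection_profile$counts
    full
  }
  c_it <- counts_for("itwiner")
  c_en <- counts_for("en")
  blk <- co$truth$corr_block
  p <- suppressWarnings(stats::wilcox.test(c_it[blk], c_en[blk], paired = TRUE,
                                           alternative = "greater")$p.value)
  expect_lt(p, 0.05)
})

test_that("random forest on DEG features separates a strong mean-shift cohort", {
  co <- generate_cohort(n_per_class = 30, p_genes = 100, block_size = 0,
                        n_shift_genes = 10, shift = 2, seed = 8)
  br <- run_benchmark(co$expression, co$annotation, feature_source = "deg_top50",
                      classifiers = "RF", n_runs = 5, seed = 3, n_top = 20)
  expect_gt(br$summary$accuracy_median, 0.9)
})
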