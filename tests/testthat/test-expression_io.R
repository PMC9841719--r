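test_that("expression matrices round-trip through delimited text and are validated", {
  m <- matrix(c(1.5, 2, 3, 4, 5, 6, 7.25, 8, 9, 10, 11, 12), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, tsv)
  expect_message(m2 <- read_expression_matrix(tsv), "3 genes x 4 samples")
  expect_identical(dim(m2), c(3L, 4L))
  expect_equal(m2, m)

  # transposed layout reads back to genes x samples
  csv <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(sample_id = colnames(m), t(m))
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  m3 <- suppressMessages(read_expression_matrix(csv, orientation = "samples_rows"))
  expect_equal(unname(m3), unname(m))

  # duplicated gene ID is a hard error naming the ID
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gX\t1\t2", "gX\t3\t4"), bad)
  expect_error(read_expression_matrix(bad), "gX")

  # non-numeric cell names the column
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\toops", "gB\t3\t4"), bad2)
  expect_error(read_expression_matrix(bad2), "s2")

  expect_error(validate_expression_matrix(matrix(c(1, Inf), 1,
                                                 dimnames = list("g", c("a", "b")))),
               "finite")
})

test_that("constant-gene filter drops exactly the zero-variance genes and is idempotent", {
  set.seed(3)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  m[4, ] <- 5.0
  expect_message(f <- filter_constant_genes(m), "removed 1 of 10")
  expect_identical(nrow(f), 9L)
  expect_identical(rownames(f), rownames(m)[-4])       # order preserved
  expect_equal(suppressMessages(filter_constant_genes(f)), f)  # idempotent

  clean <- m[-4, , drop = FALSE]
  expect_equal(suppressMessages(filter_constant_genes(clean)), clean)

  allconst <- matrix(1, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_error(filter_constant_genes(allconst), "all genes are constant")
})

test_that("genome-scale fixture with planted constant genes filters to the expected count", {
  # 39,103 genes of which 1,599 are planted constant -> 37,504 survive
  set.seed(7)
  n_genes <- 39103L; n_const <- 1599L
  m <- matrix(rnorm(n_genes * 6L), n_genes, 6L,
              dimnames = list(sprintf("g%05d", seq_len(n_genes)), paste0("s", 1:6)))
  const_rows <- sample.int(n_genes, n_const)
  m[const_rows, ] <- rep(rnorm(n_const), times = 6L)
  f <- suppressMessages(filter_constant_genes(m))
  expect_identical(nrow(f), 37504L)
})

test_that("balanced datasets replicate PM everywhere and partition P disjointly", {
  ann <- make_ann(c(sprintf("p%02d", 1:80), sprintf("m%02d", 1:30)),
                  rep(c("P", "PM"), c(80, 30)))
  ds <- make_balanced_datasets(ann, n_partitions = 3, sizes = c(30, 25, 25), seed = 5)
  expect_identical(lengths(ds$partitions), c(D1 = 60L, D2 = 55L, D3 = 55L))
  pm <- ann$sample_id[ann$class == "PM"]
  p_subsets <- lapply(ds$partitions, setdiff, y = pm)
  for (part in ds$partitions) expect_true(all(pm %in% part))   # PM replicated
  expect_identical(sort(unname(unlist(p_subsets))),
                   sort(ann$sample_id[ann$class == "P"]))
  for (i in 1:2) for (j in (i + 1):3)
    expect_length(intersect(p_subsets[[i]], p_subsets[[j]]), 0)

  # default near-equal sizes differ by at most one
  ds2 <- make_balanced_datasets(ann, n_partitions = 3, seed = 5)
  expect_lte(diff(range(ds2$p_sizes)), 1L)

  # determinism and the single-partition case
  expect_identical(make_balanced_datasets(ann, 3, c(30, 25, 25), seed = 5)$partitions,
                   ds$partitions)
  ann1 <- make_ann(c(sprintf("p%02d", 1:30), sprintf("m%02d", 1:30)),
                   rep(c("P", "PM"), each = 30))
  ds1 <- make_balanced_datasets(ann1, n_partitions = 1, seed = 2)
  expect_length(ds1$partitions[[1]], 60L)

  expect_error(make_balanced_datasets(ann1, n_partitions = 31, seed = 1), "exceeds")
  expect_error(make_balanced_datasets(ann, 3, sizes = c(40, 25, 25), seed = 1), "sum")
})

test_that("stratified splits allocate round(fraction * n) per class, deterministically", {
  ann <- make_ann(c(sprintf("p%02d", 1:30), sprintf("m%02d", 1:30)),
                  rep(c("P", "PM"), each = 30))
  sp <- stratified_split(ann$sample_id, ann, fraction = 0.7, seed = 4)
  cls_tr <- ann$class[match(sp$train_ids, ann$sample_id)]
  cls_te <- ann$class[match(sp$test_ids, ann$sample_id)]
  expect_identical(as.vector(table(cls_tr)), c(21L, 21L))
  expect_identical(as.vector(table(cls_te)), c(9L, 9L))
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), ann$sample_id)

  # same seed reproduces; different seeds differ on this fixture
  expect_identical(stratified_split(ann$sample_id, ann, 0.7, seed = 4), sp)
  sp2 <- stratified_split(ann$sample_id, ann, 0.7, seed = 5)
  expect_false(identical(sp$train_ids, sp2$train_ids))

  ann4 <- make_ann(c(paste0("p", 1:4), paste0("m", 1:4)), rep(c("P", "PM"), each = 4))
  sp4 <- stratified_split(ann4$sample_id, ann4, fraction = 0.5, seed = 1)
  expect_identical(as.vector(table(ann4$class[match(sp4$train_ids, ann4$sample_id)])),
                   c(2L, 2L))

  ann_bad <- make_ann(c("p1", "m1", "m2"), c("P", "PM", "PM"))
  expect_error(stratified_split(ann_bad$sample_id, ann_bad, 0.7, 1), "fewer than 2")
})

test_that("class coding and log-CPM helper behave as documented", {
  expect_identical(encode_class(c("P", "PM", "P")), c(1L, 0L, 1L))
  expect_error(encode_class(c("P", "X")), "unknown class")

  counts <- matrix(c(100, 900, 50, 950), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lc <- normalize_log_cpm(counts)
  expect_equal(lc["g1", "s1"], log2(100 / 1000 * 1e6 + 1))
  expect_error(normalize_log_cpm(-counts), "nonnegative")
})

test_that("annotation validation enforces schema and survival coupling", {
  expect_error(validate_annotation(data.frame(sample_id = "a")), "class")
  expect_error(validate_annotation(make_ann(c("a", "a"), c("P", "PM"))), "duplicated")
  expect_error(validate_annotation(make_ann("a", "Q")), "P")
  expect_error(validate_annotation(cbind(make_ann("a", "P"), surv_event = TRUE)),
               "surv_time")
  ok <- validate_annotation(make_ann(c("a", "b"), c("P", "PM")))
  expect_s3_class(ok$class, "factor")
})
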