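# End-to-end orchestration: data -> filter -> balanced datasets ->
# exploratory tables -> DEG ranking -> the three classification approaches.

#' Read a pipeline run configuration
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`). See [run_pipeline()] for the
#' recognized fields.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.stage_seed <- function(master, offset) as.integer(master %% 1e6L) + offset

#' Run the full analysis pipeline
#'
#' Stages: load (or simulate) data; drop constant genes; build balanced
#' undersampled datasets; clinical summary and survival log-rank tables;
#' per-dataset DEG ranking with top-k sets and cross-dataset overlaps; the
#' requested benchmark approaches per dataset; a JSON manifest indexing all
#' outputs. All randomness derives from `config$seed` via fixed per-stage
#' offsets, so a rerun with the same config is byte-identical.
#'
#' @param config Named list (or a path readable by [read_run_config()]).
#'   Fields: `seed`; either `expression` + `annotation` file paths or a
#'   `synthetic` list of [generate_cohort()] arguments; optional
#'   `n_partitions` (default 3), `partition_sizes`, `n_runs` (default 100),
#'   `n_top` (default 50), `classifiers`, `approaches` (subset of
#'   `deg_top50`, `en_top50`, `itwiner_top50`, `full_regularized`),
#'   `de_method`, `paper_mode`.
#' @param out_dir Output directory.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stop("config must set a seed")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  files <- character(0)
  tick <- function(stage) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
  }

  # -- data ------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    args$seed <- .stage_seed(seed, 11L)
    cohort <- do.call(generate_cohort, args)
    m <- cohort$expression
    ann <- validate_annotation(cohort$annotation)
    cpaths <- write_cohort(cohort, file.path(out_dir, "cohort"))
    files <- c(files, cpaths)
  } else {
    if (is.null(config$expression) || is.null(config$annotation))
      stop("config must provide either a 'synthetic' block or 'expression' + 'annotation' paths")
    m <- read_expression_matrix(config$expression)
    ann <- read_sample_annotation(config$annotation)
  }
  ann <- ann[ann$sample_id %in% colnames(m), , drop = FALSE]
  tick("data")

  # -- filter ----------------------------------------------------------
  m <- filter_constant_genes(m)
  tick("filter")

  # -- balanced datasets ----------------------------------------------
  n_part <- if (is.null(config$n_partitions)) 3L else as.integer(config$n_partitions)
  ds <- make_balanced_datasets(ann, n_partitions = n_part,
                               sizes = config$partition_sizes,
                               seed = .stage_seed(seed, 23L))
  tick("balanced_datasets")

  # -- exploratory -----------------------------------------------------
  clin <- clinical_summary_table(ann, ds)
  f <- file.path(out_dir, "clinical_summary.csv")
  utils::write.csv(clin, f, row.names = FALSE, quote = FALSE)
  files <- c(files, clinical_summary = f)
  if (all(c("surv_time", "surv_event") %in% names(ann))) {
    sv <- do.call(rbind, lapply(names(ds$partitions), function(dn) {
      sub <- ann[ann$sample_id %in% ds$partitions[[dn]], ]
      lr <- logrank_test(sub$surv_time, sub$surv_event, sub$class)
      data.frame(dataset = dn, comparison = "P_vs_PM",
                 chi_square = lr$chi_square, p_value = lr$p_value)
    }))
    f <- file.path(out_dir, "survival_logrank.csv")
    utils::write.csv(sv, f, row.names = FALSE, quote = FALSE)
    files <- c(files, survival_logrank = f)
  }
  tick("exploratory")

  # -- DEG ranking -----------------------------------------------------
  n_top <- if (is.null(config$n_top)) 50L else as.integer(config$n_top)
  de_method <- if (is.null(config$de_method)) "rank_sum" else config$de_method
  top_sets <- list()
  for (dn in names(ds$partitions)) {
    de <- de_test_per_gene(m, ann, method = de_method,
                           sample_ids = ds$partitions[[dn]])
    f <- file.path(out_dir, paste0("de_results_", dn, ".csv"))
    write_de_results(de, f)
    files <- c(files, f)
    top_sets[[dn]] <- top_k_by_pvalue(de, min(n_top, nrow(de)))
  }
  if (length(top_sets) >= 2L) {
    ov <- overlap_counts(top_sets)
    f <- file.path(out_dir, "deg_overlap_counts.csv")
    utils::write.csv(data.frame(region = names(ov), count = as.integer(ov)),
                     f, row.names = FALSE, quote = FALSE)
    files <- c(files, deg_overlap = f)
  }
  tick("deg_ranking")

  # -- benchmarks ------------------------------------------------------
  approaches <- config$approaches
  if (is.null(approaches)) approaches <- c("deg_top50", "en_top50", "itwiner_top50")
  n_runs <- if (is.null(config$n_runs)) 100L else as.integer(config$n_runs)
  classifiers <- config$classifiers
  if (is.null(classifiers)) classifiers <- c("DT", "svmL", "svmR", "LR", "RF")
  paper_mode <- isTRUE(config$paper_mode)
  for (dn in names(ds$partitions)) {
    acc_by_approach <- list()
    for (ap in approaches) {
      br <- run_benchmark(m, ann, sample_ids = ds$partitions[[dn]],
                          feature_source = ap, classifiers = classifiers,
                          n_runs = n_runs, n_top = n_top,
                          seed = .stage_seed(seed, 101L),
                          de_method = de_method, paper_mode = paper_mode)
      f <- file.path(out_dir, paste0("benchmark_", dn, "_", ap, ".csv"))
      utils::write.csv(br$summary, f, row.names = FALSE, quote = FALSE)
      files <- c(files, f)
      if (!is.null(br$selection_profile)) {
        f2 <- file.path(out_dir, paste0("selection_profile_", dn, "_", ap, ".csv"))
        utils::write.csv(data.frame(gene_id = names(br$selection_profile$counts),
                                    count = br$selection_profile$counts,
                                    row.names = NULL),
                         f2, row.names = FALSE, quote = FALSE)
        files <- c(files, f2)
      }
      for (cl in unique(br$runs$classifier))
        acc_by_approach[[paste(ap, cl, sep = "_")]] <-
          br$runs$accuracy[br$runs$classifier == cl]
    }
    if (length(acc_by_approach) >= 2L) {
      pw <- compare_accuracies_pairwise(acc_by_approach)
      f <- file.path(out_dir, paste0("accuracy_pairwise_", dn, ".csv"))
      utils::write.csv(data.frame(method = rownames(pw), pw, check.names = FALSE),
                       f, row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
  }
  tick("benchmark")

  manifest <- list(
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("itwiner")),
    penalty_mode = "factor",
    timings_sec = timings,
    datasets = lapply(ds$partitions, length),
    files = unname(files))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("pipeline finished but outputs are missing: ",
                            paste(missing, collapse = ", "))
  invisible(manifest)
}
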