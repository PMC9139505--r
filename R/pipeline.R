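#' Pipeline configuration
#'
#' One document controlling the full experiment. Either `simulate` (a
#' [cohort_config()] or a list of its arguments) or `cells_dir` +
#' `manifest` must be given. Defaults mirror the study constants:
#' 0.50 um/px, solidity cutoff 0.84, 8-108 um^2 size window, 5000
#' clustering cells per class, importance threshold 0.02, 1:1 patient
#' split, 100 repeats.
#'
#' @param simulate a [cohort_config()] (or argument list) to generate a
#'   synthetic cohort, or `NULL` to read data from disk.
#' @param cells_dir directory of per-ROI cell-table CSVs (ignored when
#'   `simulate` is given).
#' @param manifest path to a manifest JSON (ignored when `simulate` is
#'   given).
#' @param solidity_min,area_window_um2 QC thresholds.
#' @param n_per_class clustering subsample size per class.
#' @param allow_smaller take whole class pools smaller than
#'   `n_per_class` instead of erroring.
#' @param cutoff `"auto"` (optimize on the training ROIs) or a numeric
#'   cutoff in um^2.
#' @param strategies feature strategies to train and compare.
#' @param n_repeats repeated-splitting count.
#' @param sel_threshold importance threshold for the selected strategy.
#' @param nrounds boosting rounds.
#' @param master_seed master integer seed for every random stage.
#' @param out_dir output directory.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = cohort_config(),
                            cells_dir = NULL, manifest = NULL,
                            solidity_min = 0.84,
                            area_window_um2 = c(8, 108),
                            n_per_class = 5000, allow_smaller = FALSE,
                            cutoff = "auto",
                            strategies = c("unsupervised", "mixed",
                                           "supervised", "fused",
                                           "selected"),
                            n_repeats = 100, sel_threshold = 0.02,
                            nrounds = 100, master_seed = 1L,
                            out_dir = tempfile("cellpheno-run-")) {
  if (is.null(simulate) && (is.null(cells_dir) || is.null(manifest)))
    stop("either `simulate` or both `cells_dir` and `manifest` required",
         call. = FALSE)
  if (!is.null(simulate) && !inherits(simulate, "cohort_config"))
    simulate <- do.call(cohort_config, simulate)
  structure(list(simulate = simulate, cells_dir = cells_dir,
                 manifest = manifest, solidity_min = solidity_min,
                 area_window_um2 = area_window_um2,
                 n_per_class = n_per_class, allow_smaller = allow_smaller,
                 cutoff = cutoff, strategies = strategies,
                 n_repeats = n_repeats, sel_threshold = sel_threshold,
                 nrounds = nrounds, master_seed = as.integer(master_seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with any subset of [pipeline_config()]'s
#'   fields; `simulate` may be a nested object of [cohort_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$simulate)) raw$simulate <- as.list(raw$simulate)
  do.call(pipeline_config, raw)
}

#' Run the full experiment
#'
#' Orchestrates simulate (or load), QC, phenotype discovery on the
#' training side of a primary 1:1 patient split, label propagation,
#' cutoff optimization, per-ROI featurization, per-strategy training and
#' evaluation on the primary split, repeated-splitting evaluation, and
#' the pairwise one-tailed t-test comparison of strategy accuracies.
#' All artifacts (features CSV, phenotype model JSON, per-strategy
#' models and reports, the repeated-split summary, the t-test table, and
#' a stage log with seeds) are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_result` with elements `config`,
#'   `split`, `phenotype_model`, `cutoff`, `features`, `primary_eval`
#'   (per strategy), `repeated` (a `repeated_split_report`), `ttest`
#'   (pairwise upper-tail p values on repeated accuracies), `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, paste0(...)), file = log_path,
        append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(name, "ERROR: ", conditionMessage(e))
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seed <- config$master_seed
  cat(sprintf("# cellpheno run, master seed %d\n", seed), file = log_path)

  cohort <- stage("input", {
    if (!is.null(config$simulate)) {
      cfg <- config$simulate
      cfg$seed <- derive_seed(seed, "simulate")
      log_line("simulate", "seed ", cfg$seed)
      generate_cohort(cfg)
    } else {
      log_line("load", config$cells_dir)
      paths <- list.files(config$cells_dir, pattern = "\\.csv$",
                          full.names = TRUE)
      cells <- lapply(paths, read_cell_table)
      names(cells) <- vapply(cells, function(tb) attr(tb, "roi_id"), "")
      list(manifest = read_manifest(config$manifest), cells = cells)
    }
  })

  qc <- stage("qc", {
    out <- lapply(cohort$cells, filter_cells,
                  solidity_min = config$solidity_min,
                  area_window_um2 = config$area_window_um2)
    log_line("qc", sum(vapply(out, nrow, 1L)), " of ",
             sum(vapply(cohort$cells, nrow, 1L)), " cells retained")
    out
  })

  rois <- manifest_rois(cohort$manifest)
  split <- stage("split", split_cohort(cohort$manifest,
                                       seed = derive_seed(seed, "primary-split")))
  log_line("split", length(split$train), " train / ", length(split$test),
           " test patients")
  train_rois <- rois$roi_id[rois$patient_id %in% split$train]

  pheno <- stage("phenotype", {
    by_class <- lapply(stats::setNames(disease_classes(), disease_classes()),
                       function(cls)
                         qc[intersect(rois$roi_id[rois$class == cls],
                                      train_rois)])
    m <- fit_phenotype_model(by_class, n_per_class = config$n_per_class,
                             seed = derive_seed(seed, "phenotype"),
                             allow_smaller = config$allow_smaller)
    write_phenotype_model(m, file.path(config$out_dir,
                                       "phenotype_model.json"))
    log_line("phenotype", "sample ", length(m$cluster), " cells, seed ",
             m$seed)
    m
  })

  labeled <- stage("propagate", lapply(qc, propagate_labels, model = pheno))

  cutoff <- stage("cutoff", {
    if (identical(config$cutoff, "auto")) {
      cs <- optimize_size_cutoff(labeled[train_rois])
      jsonlite::write_json(list(optimal_cutoff_um2 = cs$optimal_cutoff_um2,
                                objective = cs$objective,
                                class_ratios = as.list(cs$class_ratios)),
                           file.path(config$out_dir, "cutoff.json"),
                           auto_unbox = TRUE, digits = NA)
      log_line("cutoff", "optimized: ", cs$optimal_cutoff_um2, " um^2")
      cs$optimal_cutoff_um2
    } else as.numeric(config$cutoff)
  })

  features <- stage("featurize", {
    f <- featurize_cohort(labeled, cutoff, cohort$manifest)
    write_features(f, file.path(config$out_dir, "features.csv"))
    f
  })

  primary_eval <- stage("train-eval", {
    tr <- features$patient_id %in% split$train
    te <- features$patient_id %in% split$test
    out <- list()
    for (st in config$strategies) {
      seed_st <- derive_seed(seed, "train", st)
      subset <- strategy_features(st, features[tr, , drop = FALSE],
                                  features$label[tr], seed_st,
                                  config$sel_threshold)
      model <- train_classifier(features[tr, , drop = FALSE],
                                features$label[tr], feature_subset = subset,
                                seed = seed_st, nrounds = config$nrounds)
      write_diagnosis_model(model, file.path(config$out_dir, "models", st))
      ev <- evaluate_model(model, features[te, , drop = FALSE],
                           features$label[te])
      jsonlite::write_json(
        list(strategy = st, accuracy = ev$accuracy,
             macro_auc = ev$macro_auc,
             per_class_auc = as.list(ev$per_class_auc),
             confusion = as.data.frame.matrix(unclass(ev$confusion)),
             n_test_rois = ev$n_test_rois),
        file.path(config$out_dir, paste0("report_", st, ".json")),
        auto_unbox = TRUE, digits = NA)
      log_line("train-eval", st, ": accuracy ", round(ev$accuracy, 4),
               ", macro AUC ", round(ev$macro_auc, 4))
      out[[st]] <- ev
    }
    out
  })

  repeated <- stage("repeat-split", {
    r <- repeated_split_eval(cohort$manifest, features,
                             strategies = config$strategies,
                             n_repeats = config$n_repeats,
                             master_seed = derive_seed(seed, "repeats"),
                             nrounds = config$nrounds,
                             threshold = config$sel_threshold)
    jsonlite::write_json(list(summary = r$summary, results = r$results),
                         file.path(config$out_dir, "repeated_splits.json"),
                         auto_unbox = TRUE, digits = NA)
    r
  })

  ttest <- stage("ttest", {
    st <- config$strategies
    p <- matrix(NA_real_, length(st), length(st), dimnames = list(st, st))
    for (a in st) for (b in st) if (a != b) {
      p[a, b] <- one_tailed_ttest(
        repeated$results$accuracy[repeated$results$strategy == a],
        repeated$results$accuracy[repeated$results$strategy == b])
    }
    utils::write.csv(as.data.frame(p),
                     file.path(config$out_dir, "ttest_accuracy.csv"))
    p
  })

  structure(list(config = config, split = split, phenotype_model = pheno,
                 cutoff = cutoff, features = features,
                 primary_eval = primary_eval, repeated = repeated,
                 ttest = ttest, out_dir = config$out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$out_dir, "\n")
  cat(sprintf("cutoff: %.1f um^2\n", x$cutoff))
  cat("primary split evaluation:\n")
  for (st in names(x$primary_eval))
    cat(sprintf("  %-12s accuracy %.3f  macro AUC %.3f\n", st,
                x$primary_eval[[st]]$accuracy,
                x$primary_eval[[st]]$macro_auc))
  cat(sprintf("repeated splitting (%d repeats):\n", x$repeated$n_repeats))
  print(x$repeated$summary, digits = 4, row.names = FALSE)
  invisible(x)
}
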