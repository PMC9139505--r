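#' Patient-level 1:1 stratified cohort split
#'
#' Splits patients (never ROIs) into training and testing halves. Within
#' every joint stratum of disease class and the binary covariates,
#' patients are divided as evenly as possible; single leftover patients
#' from odd strata are pooled within their disease class, shuffled, and
#' assigned alternately so per-class train/test counts differ by at most
#' one. This balanced joint-stratum assignment plays the role of
#' covariate matching between the cohorts.
#'
#' @param manifest a [cohort_manifest()].
#' @param seed integer seed.
#' @param covariates covariate column names used for stratification;
#'   defaults to all covariates in the manifest.
#' @return an object of class `split_spec`: `train`, `test` (patient
#'   ids), `seed`, `strata` (per-patient stratum record).
#' @export
split_cohort <- function(manifest, seed = 1L, covariates = NULL) {
  pts <- manifest_patients(manifest)
  for (cls in disease_classes())
    if (sum(pts$class == cls) < 2)
      stop("need >= 2 patients in class ", cls, call. = FALSE)
  cov_cols <- covariates %||%
    setdiff(names(pts), c("patient_id", "class", "n_slides", "n_rois"))
  stratum <- apply(pts[, c("class", cov_cols), drop = FALSE], 1,
                   paste, collapse = "|")
  train <- character(0); test <- character(0)
  with_seed(seed, {
    for (cls in disease_classes()) {
      leftovers <- character(0)
      for (st in unique(stratum[pts$class == cls])) {
        ids <- sample(pts$patient_id[stratum == st & pts$class == cls])
        half <- length(ids) %/% 2
        train <- c(train, ids[seq_len(half)])
        test <- c(test, ids[half + seq_len(half)])
        if (length(ids) %% 2 == 1) leftovers <- c(leftovers, ids[length(ids)])
      }
      if (length(leftovers) > 0) {
        leftovers <- sample(leftovers)
        to_train <- seq_along(leftovers) %% 2 == (stats::runif(1) < 0.5)
        train <- c(train, leftovers[to_train])
        test <- c(test, leftovers[!to_train])
      }
    }
  })
  structure(list(train = sort(train), test = sort(test), seed = seed,
                 strata = stats::setNames(stratum, pts$patient_id)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test patients (seed %d)\n",
              length(x$train), length(x$test), x$seed))
  invisible(x)
}

#' @noRd
features_to_matrix <- function(features, feature_subset) {
  missing_cols <- setdiff(feature_subset, names(features))
  if (length(missing_cols) > 0)
    stop("feature column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  as.matrix(features[, feature_subset, drop = FALSE])
}

#' Train the boosted-tree diagnosis model
#'
#' A gradient-boosted decision-tree ensemble (XGBoost, multiclass
#' softprob) over a named feature subset. Missing feature values are
#' routed natively by the trees. Training is deterministic given the
#' seed (single-threaded).
#'
#' @param features a data.frame of per-ROI features (rows = ROIs).
#' @param labels disease class per row, in [disease_classes()].
#' @param feature_subset names of the feature columns to use.
#' @param seed integer seed.
#' @param nrounds boosting rounds (default 100).
#' @param params extra XGBoost parameters; defaults `max_depth = 6`,
#'   `eta = 0.3`.
#' @return an object of class `diagnosis_model`.
#' @export
train_classifier <- function(features, labels,
                             feature_subset = feature_names("all"),
                             seed = 1L, nrounds = 100, params = list()) {
  classes <- disease_classes()
  y <- factor(labels, levels = classes)
  if (any(is.na(y))) stop("unknown disease label in training data",
                          call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("training set has a single class", call. = FALSE)
  x <- features_to_matrix(features, feature_subset)
  p <- utils::modifyList(
    list(objective = "multi:softprob", num_class = length(classes),
         max_depth = 6, eta = 0.3, nthread = 1, seed = as.integer(seed)),
    params)
  booster <- with_seed(seed, {
    dm <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
    xgboost::xgb.train(params = p, data = dm, nrounds = nrounds, verbose = 0)
  })
  structure(list(booster = booster, feature_names = feature_subset,
                 classes = classes, seed = as.integer(seed),
                 params = c(p, nrounds = nrounds)),
            class = "diagnosis_model")
}

#' @rdname train_classifier
#' @param object a `diagnosis_model`.
#' @param newdata a data.frame containing the model's feature columns.
#' @param ... unused.
#' @return `predict()` returns an n x 3 matrix of class probabilities
#'   (columns in class order), each row summing to 1.
#' @export
predict.diagnosis_model <- function(object, newdata, ...) {
  x <- features_to_matrix(newdata, object$feature_names)
  probs <- predict(object$booster, xgboost::xgb.DMatrix(x))
  colnames(probs) <- object$classes
  probs
}

#' @export
print.diagnosis_model <- function(x, ...) {
  cat(sprintf(
    "<diagnosis_model> XGBoost (%d rounds, seed %d) on %d feature(s)\n",
    x$params[["nrounds"]], x$seed, length(x$feature_names)))
  cat(paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Save and load a diagnosis model
#'
#' The booster is stored in XGBoost's portable JSON model format with a
#' sidecar JSON holding feature names, class order, and seed.
#'
#' @param model a `diagnosis_model`.
#' @param dir output directory (created if needed).
#' @return `write_diagnosis_model` returns `dir` invisibly;
#'   `read_diagnosis_model` returns a `diagnosis_model`.
#' @export
write_diagnosis_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.json"))
  jsonlite::write_json(list(feature_names = model$feature_names,
                            classes = model$classes, seed = model$seed),
                       file.path(dir, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_diagnosis_model
#' @export
read_diagnosis_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  structure(list(booster = xgboost::xgb.load(file.path(dir, "booster.json")),
                 feature_names = meta$feature_names, classes = meta$classes,
                 seed = as.integer(meta$seed), params = list()),
            class = "diagnosis_model")
}

#' Impurity-based feature selection
#'
#' Fits an ensemble of randomized trees (extremely-randomized splits,
#' impurity importance) on the training features, normalizes the
#' importances to sum to one, and keeps features with importance at or
#' above the threshold (0.02 by default), preserving the canonical
#' feature order. Missing values are median-imputed for the importance
#' fit only (the downstream boosted trees see the unimputed features).
#'
#' @param features data.frame of per-ROI features.
#' @param labels disease class per row.
#' @param threshold importance threshold in (0, 1).
#' @param seed integer seed.
#' @param feature_subset candidate features (default all 20).
#' @param num_trees ensemble size.
#' @return a list of class `feature_selection`: `selected` (names),
#'   `importance` (named numeric, sums to 1), `threshold`.
#' @export
select_features <- function(features, labels, threshold = 0.02, seed = 1L,
                            feature_subset = feature_names("all"),
                            num_trees = 500) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("feature selection needs >= 2 classes", call. = FALSE)
  x <- as.data.frame(features_to_matrix(features, feature_subset))
  for (j in seq_along(x)) {
    v <- x[[j]]
    if (anyNA(v)) {
      med <- stats::median(v, na.rm = TRUE)
      v[is.na(v)] <- if (is.finite(med)) med else 0
      x[[j]] <- v
    }
  }
  y <- factor(labels, levels = disease_classes())
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        importance = "impurity", splitrule = "extratrees",
                        seed = as.integer(seed), num.threads = 1)
  imp <- fit$variable.importance
  imp <- if (sum(imp) > 0) imp / sum(imp) else
    stats::setNames(rep(1 / length(imp), length(imp)), names(imp))
  selected <- feature_subset[imp[feature_subset] >= threshold]
  structure(list(selected = selected,
                 importance = imp[feature_subset],
                 threshold = threshold),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d of %d features at threshold %.3g\n",
              length(x$selected), length(x$importance), x$threshold))
  imp <- sort(x$importance, decreasing = TRUE)
  print(round(imp, 4))
  invisible(x)
}

#' Evaluate a diagnosis model on a test set
#'
#' Accuracy from argmax predictions; per-class one-vs-rest ROC AUC from
#' the predicted probabilities (trapezoidal); macro AUC as their
#' unweighted mean. A class absent from the test labels gets a missing
#' AUC and the macro average runs over the present classes with a
#' warning.
#'
#' @param model a `diagnosis_model`.
#' @param features test feature data.frame.
#' @param labels true disease class per row.
#' @return an object of class `eval_report`: `accuracy`, `macro_auc`,
#'   `per_class_auc`, `confusion` (3 x 3, rows = truth), `n_test_rois`.
#' @export
evaluate_model <- function(model, features, labels) {
  stopifnot(nrow(features) > 0)
  probs <- predict(model, features)
  classes <- model$classes
  pred <- classes[max.col(probs, ties.method = "first")]
  truth <- factor(labels, levels = classes)
  confusion <- table(truth = truth,
                     predicted = factor(pred, levels = classes))
  acc <- mean(pred == as.character(truth))
  aucs <- vapply(classes, function(cls) {
    resp <- as.integer(truth == cls)
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = resp,
                                   predictor = probs[, cls],
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  }, numeric(1))
  if (anyNA(aucs))
    warning("class(es) absent from test labels: macro AUC over present ",
            "classes only", call. = FALSE)
  structure(list(accuracy = acc, macro_auc = mean(aucs, na.rm = TRUE),
                 per_class_auc = aucs, confusion = confusion,
                 n_test_rois = nrow(features)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f, macro AUC %.3f (%d test ROIs)\n",
              x$accuracy, x$macro_auc, x$n_test_rois))
  print(x$confusion)
  invisible(x)
}

#' Repeated patient-level splitting evaluation
#'
#' Repeats the 1:1 patient-level split `n_repeats` times (100 by
#' default). Within each repeat every feature strategy sees the
#' identical split; a model is trained on the training-side ROI features
#' and evaluated on the test side. Reports per-repeat metrics and the
#' per-strategy mean and SD of accuracy and macro AUC.
#'
#' Strategies: `"unsupervised"`, `"mixed"`, `"supervised"`, `"fused"`
#' (all 20 features), and `"selected"` (impurity-based selection refit
#' on each repeat's training side).
#'
#' @param manifest a [cohort_manifest()].
#' @param features per-ROI feature data.frame with `patient_id` and
#'   `label` columns (see [featurize_cohort()]).
#' @param strategies character vector of strategy names.
#' @param n_repeats number of random splits.
#' @param master_seed integer; repeat `r` uses a seed derived from
#'   (master_seed, r).
#' @param nrounds,params passed to [train_classifier()].
#' @param threshold importance threshold for the `"selected"` strategy.
#' @return an object of class `repeated_split_report`: `results` (one
#'   row per repeat x strategy), `summary` (mean/SD per strategy),
#'   `n_repeats`, `master_seed`.
#' @export
repeated_split_eval <- function(manifest, features,
                                strategies = c("unsupervised", "mixed",
                                               "supervised", "fused",
                                               "selected"),
                                n_repeats = 100, master_seed = 1L,
                                nrounds = 100, params = list(),
                                threshold = 0.02) {
  stopifnot(all(c("patient_id", "label") %in% names(features)))
  rows <- list()
  for (r in seq_len(n_repeats)) {
    seed_r <- derive_seed(master_seed, "split", r)
    split <- split_cohort(manifest, seed = seed_r)
    tr <- features$patient_id %in% split$train
    te <- features$patient_id %in% split$test
    for (st in strategies) {
      subset <- strategy_features(st, features[tr, , drop = FALSE],
                                  features$label[tr], seed_r, threshold)
      model <- train_classifier(features[tr, , drop = FALSE],
                                features$label[tr], feature_subset = subset,
                                seed = seed_r, nrounds = nrounds,
                                params = params)
      rep_eval <- evaluate_model(model, features[te, , drop = FALSE],
                                 features$label[te])
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, strategy = st, accuracy = rep_eval$accuracy,
        macro_auc = rep_eval$macro_auc, n_test_rois = rep_eval$n_test_rois,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(strategies, function(st) {
    sub <- results[results$strategy == st, ]
    data.frame(strategy = st,
               mean_accuracy = mean(sub$accuracy),
               sd_accuracy = stats::sd(sub$accuracy),
               mean_macro_auc = mean(sub$macro_auc),
               sd_macro_auc = stats::sd(sub$macro_auc),
               stringsAsFactors = FALSE)
  }))
  structure(list(results = results, summary = summary,
                 n_repeats = n_repeats, master_seed = master_seed),
            class = "repeated_split_report")
}

#' @noRd
strategy_features <- function(strategy, train_features, train_labels,
                              seed, threshold = 0.02) {
  switch(strategy,
         unsupervised = feature_names("unsupervised"),
         mixed = feature_names("mixed"),
         supervised = feature_names("supervised"),
         fused = feature_names("all"),
         selected = select_features(train_features, train_labels,
                                    threshold = threshold,
                                    seed = seed)$selected,
         stop("unknown strategy: ", strategy, call. = FALSE))
}

#' @export
print.repeated_split_report <- function(x, ...) {
  cat(sprintf("<repeated_split_report> %d repeats (master seed %d)\n",
              x$n_repeats, x$master_seed))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' One-tailed (upper) Welch t-test between accuracy vectors
#'
#' Tests whether `mean(acc_a) > mean(acc_b)` using the unequal-variance
#' two-sample t statistic (upper-tail p value). When both samples have
#' zero variance: equal means give `p = 0.5` by convention, otherwise
#' the p value degenerates to 0 or 1 with the sign of the difference.
#'
#' @param acc_a,acc_b numeric vectors of per-repeat metrics
#'   (length >= 2).
#' @return the upper-tail p value.
#' @export
one_tailed_ttest <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) >= 2, length(acc_b) >= 2)
  va <- stats::var(acc_a); vb <- stats::var(acc_b)
  dm <- mean(acc_a) - mean(acc_b)
  if (va == 0 && vb == 0) {
    return(if (dm == 0) 0.5 else if (dm > 0) 0 else 1)
  }
  na <- length(acc_a); nb <- length(acc_b)
  se2 <- va / na + vb / nb
  t_stat <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  stats::pt(t_stat, df, lower.tail = FALSE)
}
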