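# A manifest of `n` patients per class with identical covariates, so
# every stratum is a whole class.
flat_manifest <- function(n_per_class = 4) {
  cohort_manifest(unlist(lapply(disease_classes(), function(cls) {
    lapply(seq_len(n_per_class), function(i) {
      pid <- sprintf("%s-%02d", cls, i)
      list(id = pid, class = cls, covariates = list(grp = TRUE),
           slides = list(list(id = paste0(pid, "-S1"),
                              rois = paste0(pid, "-R", 1:2))))
    })
  }), recursive = FALSE))
}

# Linearly separable toy features for the three classes.
toy_features <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  labels <- rep(disease_classes(), each = n_per_class)
  feats <- as.data.frame(matrix(stats::rnorm(3 * n_per_class * 20),
                                ncol = 20,
                                dimnames = list(NULL, feature_names("all"))))
  feats$rt_like_ratio <- as.numeric(factor(labels, disease_classes())) +
    stats::rnorm(length(labels), 0, 0.05)
  feats$label <- labels
  feats
}

test_that("patient splits are disjoint, exhaustive, and class-balanced", {
  manifest <- small_benchmark()$manifest
  pts <- manifest_patients(manifest)
  for (seed in 1:20) {
    sp <- split_cohort(manifest, seed = seed)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), pts$patient_id)
    for (cls in disease_classes()) {
      ids <- pts$patient_id[pts$class == cls]
      expect_lte(abs(sum(sp$train %in% ids) - sum(sp$test %in% ids)), 1)
    }
  }
})

test_that("even strata are split exactly in half", {
  manifest <- flat_manifest(4)
  sp <- split_cohort(manifest, seed = 5)
  for (cls in disease_classes()) {
    expect_equal(sum(startsWith(sp$train, cls)), 2)
    expect_equal(sum(startsWith(sp$test, cls)), 2)
  }
})

test_that("splitting requires two patients per class", {
  expect_error(split_cohort(flat_manifest(1)), "need >= 2 patients")
})

test_that("the classifier fits separable toy data perfectly", {
  feats <- toy_features()
  model <- train_classifier(feats, feats$label, seed = 3, nrounds = 30)
  probs <- predict(model, feats)
  expect_equal(dim(probs), c(nrow(feats), 3))
  expect_equal(rowSums(probs), rep(1, nrow(feats)), tolerance = 1e-6)
  pred <- disease_classes()[max.col(probs)]
  expect_equal(mean(pred == feats$label), 1)
})

test_that("classifier training is seed-deterministic", {
  feats <- toy_features()
  a <- predict(train_classifier(feats, feats$label, seed = 3, nrounds = 20),
               feats)
  b <- predict(train_classifier(feats, feats$label, seed = 3, nrounds = 20),
               feats)
  expect_identical(a, b)
})

test_that("missing feature values are tolerated end to end", {
  feats <- toy_features()
  feats$l2l_nn_dist <- NA_real_
  feats$s2l_nn_dist[1:10] <- NA_real_
  model <- train_classifier(feats, feats$label, seed = 2, nrounds = 20)
  probs <- predict(model, feats)
  expect_false(anyNA(probs))
  sel <- select_features(feats, feats$label, seed = 2)
  expect_s3_class(sel, "feature_selection")
})

test_that("training rejects degenerate label sets", {
  feats <- toy_features()
  expect_error(train_classifier(feats, rep("CLL", nrow(feats))),
               "single class")
  expect_error(train_classifier(feats, rep("bogus", nrow(feats))),
               "unknown disease label")
})

test_that("diagnosis models survive a disk round trip", {
  feats <- toy_features()
  model <- train_classifier(feats, feats$label, seed = 3, nrounds = 20,
                            feature_subset = feature_names("unsupervised"))
  td <- withr::local_tempdir()
  write_diagnosis_model(model, file.path(td, "m"))
  back <- read_diagnosis_model(file.path(td, "m"))
  expect_identical(back$feature_names, model$feature_names)
  expect_equal(predict(back, feats), predict(model, feats),
               tolerance = 1e-7)
})

test_that("feature selection finds the informative feature", {
  feats <- toy_features(seed = 8)
  sel <- select_features(feats, feats$label, seed = 4)
  expect_equal(sum(sel$importance), 1)
  expect_identical(names(sel$importance), feature_names("all"))
  expect_true("rt_like_ratio" %in% sel$selected)
  expect_equal(names(which.max(sel$importance)), "rt_like_ratio")
  # selected order follows the canonical feature order
  expect_identical(sel$selected,
                   feature_names("all")[feature_names("all") %in%
                                          sel$selected])
  expect_error(select_features(feats, feats$label, threshold = 1.5),
               "threshold")
})

test_that("pure-noise features carry exchangeably small importance", {
  feats <- toy_features(seed = 9)
  sel <- select_features(feats, feats$label, seed = 5)
  noise <- setdiff(feature_names("all"), "rt_like_ratio")
  expect_true(all(sel$importance[noise] < sel$importance["rt_like_ratio"]))
})

test_that("evaluation metrics match hand-checkable extremes", {
  feats <- toy_features()
  model <- train_classifier(feats, feats$label, seed = 3, nrounds = 30)
  ev <- evaluate_model(model, feats, feats$label)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$macro_auc, 1)
  expect_equal(unname(diag(ev$confusion)), as.vector(table(feats$label)[
    disease_classes()]))
  expect_equal(sum(ev$confusion), nrow(feats))
  expect_equal(ev$n_test_rois, nrow(feats))
})

test_that("a constant predictor scores AUC 0.5 per class", {
  feats <- toy_features()
  feats$rt_like_ratio <- 0  # destroy the signal column
  const <- toy_features(n_per_class = 2, seed = 2)
  const$rt_like_ratio <- 0
  const[, feature_names("all")] <- 0
  model <- train_classifier(const, const$label, seed = 1, nrounds = 2)
  feats0 <- feats
  feats0[, feature_names("all")] <- 0
  ev <- evaluate_model(model, feats0, feats0$label)
  expect_equal(unname(ev$per_class_auc), rep(0.5, 3))
})

test_that("absent test classes yield missing AUC with a warning", {
  feats <- toy_features()
  model <- train_classifier(feats, feats$label, seed = 3, nrounds = 10)
  sub <- feats[feats$label != "RT", ]
  expect_warning(ev <- evaluate_model(model, sub, sub$label), "absent")
  expect_true(is.na(ev$per_class_auc["RT"]))
  expect_false(is.na(ev$macro_auc))
})

test_that("one_tailed_ttest covers conventions and agrees with t.test", {
  expect_equal(one_tailed_ttest(rep(0.7, 5), rep(0.7, 5)), 0.5)
  expect_equal(one_tailed_ttest(rep(0.9, 5), rep(0.1, 5)), 0)
  expect_equal(one_tailed_ttest(rep(0.1, 5), rep(0.9, 5)), 1)
  set.seed(6)
  a <- stats::rnorm(30, 0.9, 0.05)
  b <- stats::rnorm(30, 0.7, 0.05)
  expect_equal(one_tailed_ttest(a, b),
               stats::t.test(a, b, alternative = "greater")$p.value)
  expect_lt(one_tailed_ttest(a, b), 0.01)
  expect_gt(one_tailed_ttest(b, a), 0.99)
})

test_that("repeated splitting shares splits across strategies", {
  rep_eval <- repeated_split_eval(
    small_benchmark()$manifest, small_features(),
    strategies = c("unsupervised", "fused"), n_repeats = 3,
    master_seed = 17, nrounds = 20)
  res <- rep_eval$results
  expect_equal(nrow(res), 6)
  for (r in 1:3) {
    n_test <- unique(res$n_test_rois[res$repeat_id == r])
    expect_length(n_test, 1)  # same split for both strategies
  }
  expect_identical(sort(unique(res$strategy)), c("fused", "unsupervised"))
  expect_equal(nrow(rep_eval$summary), 2)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
})

test_that("repeated splitting is reproducible from the master seed", {
  a <- repeated_split_eval(small_benchmark()$manifest, small_features(),
                           strategies = "unsupervised", n_repeats = 2,
                           master_seed = 23, nrounds = 10)
  b <- repeated_split_eval(small_benchmark()$manifest, small_features(),
                           strategies = "unsupervised", n_repeats = 2,
                           master_seed = 23, nrounds = 10)
  expect_identical(a$results, b$results)
})

test_that("no patient contributes ROIs to both sides of any repeat", {
  manifest <- small_benchmark()$manifest
  feats <- small_features()
  for (r in 1:5) {
    sp <- split_cohort(manifest, seed = derive_seed(17, "split", r))
    tr_pat <- unique(feats$patient_id[feats$patient_id %in% sp$train])
    te_pat <- unique(feats$patient_id[feats$patient_id %in% sp$test])
    expect_length(intersect(tr_pat, te_pat), 0)
  }
})
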