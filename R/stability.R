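#' Clustering stability analysis over subsample sizes and seeds
#'
#' Repeats the full phenotype-discovery chain (subsample, spectral
#' clustering, naming, propagation) with varying total subsample sizes
#' and random states -- by default four runs at 15,000 cells plus one
#' run each at 9000, 12,000, 18,000, and 21,000 -- and measures, for
#' every run, the downstream diagnosis accuracy and macro AUC of the
#' unsupervised feature strategy on one fixed patient-level split, plus
#' the pairwise agreement of propagated labels between runs on a common
#' probe set of cells.
#'
#' @param cohort a [generate_cohort()] result, or a list with elements
#'   `manifest` and `cells`.
#' @param sizes total subsample sizes, one run per entry (split evenly
#'   over the three classes).
#' @param master_seed integer; run `i` uses a seed derived from
#'   `(master_seed, i)`, and the fixed split and probe set are derived
#'   from it too.
#' @param n_probe maximum number of probe cells for the agreement
#'   matrix.
#' @param nrounds boosting rounds for the downstream classifier.
#' @return an object of class `stability_report`: `runs` (data.frame
#'   run/size/seed/accuracy/macro_auc), `agreement` (symmetric matrix of
#'   propagated-label agreement), `split`.
#' @export
stability_analysis <- function(cohort,
                               sizes = c(rep(15000, 4), 9000, 12000,
                                         18000, 21000),
                               master_seed = 1L, n_probe = 20000,
                               nrounds = 100) {
  manifest <- cohort$manifest
  qc <- lapply(cohort$cells, filter_cells)
  rois <- manifest_rois(manifest)
  split <- split_cohort(manifest, seed = derive_seed(master_seed, "split"))
  train_rois <- rois$roi_id[rois$patient_id %in% split$train]
  by_class <- lapply(stats::setNames(disease_classes(), disease_classes()),
                     function(cls)
                       qc[intersect(rois$roi_id[rois$class == cls],
                                    train_rois)])
  # the cutoff depends only on sizes and class labels, not on phenotype
  # labels, so it is shared across runs
  cutoff <- optimize_size_cutoff(qc[train_rois])$optimal_cutoff_um2
  probe <- do.call(rbind, lapply(qc, function(tb)
    data.frame(area_um2 = tb$area_um2, mean_intensity = tb$mean_intensity)))
  if (nrow(probe) > n_probe) {
    probe <- probe[with_seed(derive_seed(master_seed, "probe"),
                             sample.int(nrow(probe), n_probe)), ]
  }
  runs <- list()
  probe_labels <- list()
  for (i in seq_along(sizes)) {
    seed_i <- derive_seed(master_seed, "stability", i)
    model <- fit_phenotype_model(by_class,
                                 n_per_class = floor(sizes[i] / 3),
                                 seed = seed_i)
    labeled <- lapply(qc, function(tb) propagate_labels(model, tb))
    feats <- featurize_cohort(labeled, cutoff, manifest)
    clf <- train_classifier(
      feats[feats$patient_id %in% split$train, ],
      feats$label[feats$patient_id %in% split$train],
      feature_subset = feature_names("unsupervised"),
      seed = seed_i, nrounds = nrounds)
    ev <- evaluate_model(clf, feats[feats$patient_id %in% split$test, ],
                         feats$label[feats$patient_id %in% split$test])
    runs[[i]] <- data.frame(run = i, size = sizes[i], seed = seed_i,
                            accuracy = ev$accuracy,
                            macro_auc = ev$macro_auc)
    x_z <- apply_scaler(model$scaler, probe$area_um2, probe$mean_intensity)
    probs <- propagator_probs(model$coefficients, x_z)
    probe_labels[[i]] <-
      phenotype_names()[max.col(probs, ties.method = "first")]
  }
  n_runs <- length(sizes)
  agreement <- diag(1, n_runs)
  if (n_runs > 1) {
    for (i in seq_len(n_runs - 1)) {
      for (j in seq.int(i + 1, n_runs)) {
        agreement[i, j] <- agreement[j, i] <-
          mean(probe_labels[[i]] == probe_labels[[j]])
      }
    }
  }
  structure(list(runs = do.call(rbind, runs), agreement = agreement,
                 split = split),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  print(x$runs, row.names = FALSE, digits = 4)
  off <- x$agreement[upper.tri(x$agreement)]
  if (length(off) > 0)
    cat(sprintf("pairwise label agreement: min %.4f, mean %.4f\n",
                min(off), mean(off)))
  invisible(x)
}
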