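# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# A small benchmark cohort with well-separated archetypes (12 patients,
# ~3.5k cells): big enough to cluster, small enough to keep tests fast.
small_benchmark <- function() fixture("small_benchmark", function() {
  benchmark_cohort(seed = 7, patients_per_class = 4,
                   slides_per_patient = c(1, 1), rois_per_slide = c(1, 2),
                   cells_per_roi = c(150, 280))
})

small_qc <- function() fixture("small_qc", function() {
  lapply(small_benchmark()$cells, filter_cells)
})

small_rois <- function() fixture("small_rois", function() {
  manifest_rois(small_benchmark()$manifest)
})

small_by_class <- function() fixture("small_by_class", function() {
  rois <- small_rois()
  qc <- small_qc()
  lapply(stats::setNames(disease_classes(), disease_classes()),
         function(cls) qc[rois$roi_id[rois$class == cls]])
})

small_model <- function() fixture("small_model", function() {
  fit_phenotype_model(small_by_class(), n_per_class = 400, seed = 11)
})

small_labeled <- function() fixture("small_labeled", function() {
  lapply(small_qc(), propagate_labels, model = small_model())
})

small_features <- function() fixture("small_features", function() {
  cutoff <- optimize_size_cutoff(small_labeled())$optimal_cutoff_um2
  featurize_cohort(small_labeled(), cutoff, small_benchmark()$manifest)
})

# Cell rows as a plain data.frame, without the per-pass filter report.
strip_report <- function(tab) {
  attr(tab, "filter_report") <- NULL
  as.data.frame(tab)
}

# Hand-built cell table with full control over the geometry.
make_table <- function(area_um2, intensity = 120, x = NULL, y = NULL,
                       solidity = 0.95, roi_id = "t-roi", label = "CLL",
                       resolution = 0.5, roi_px = 1000, phenotype = NULL) {
  n <- length(area_um2)
  if (is.null(x)) x <- seq_len(n) * 10
  if (is.null(y)) y <- rep(10, n)
  cells <- data.frame(
    cell_id = sprintf("c%03d", seq_len(max(n, 0))),
    area_px = area_um2 / resolution^2,
    mean_intensity = rep_len(intensity, n),
    centroid_x_um = x, centroid_y_um = y,
    solidity = rep_len(solidity, n),
    stringsAsFactors = FALSE)
  if (!is.null(phenotype)) cells$phenotype <- phenotype
  cell_table(cells, roi_id = roi_id, resolution = resolution,
             roi_width_px = roi_px, roi_height_px = roi_px,
             disease_label = label)
}

# Three tight, well-separated blobs in (area_um2, mean_intensity), with
# known generating labels, shaped like a subsample_cells() result.
blob_sample <- function(n_per = 150, seed = 5) {
  centers <- data.frame(area = c(12, 14, 60), inten = c(100, 180, 140))
  truth <- rep(phenotype_names(), each = n_per)
  set.seed(seed)
  data.frame(
    class = rep(disease_classes(), each = n_per),
    roi_id = "blob", cell_id = sprintf("b%04d", seq_len(3 * n_per)),
    area_um2 = rep(centers$area, each = n_per) + stats::rnorm(3 * n_per, 0, 0.4),
    mean_intensity = rep(centers$inten, each = n_per) +
      stats::rnorm(3 * n_per, 0, 2),
    truth_phenotype = truth,
    stringsAsFactors = FALSE)
}
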