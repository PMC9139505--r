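#' Canonical per-ROI feature names
#'
#' The 20 per-ROI features in fixed order: 6 unsupervised (per-phenotype
#' cell ratios and densities), 4 mixed (mean size, mean intensity, mean
#' nearest-neighbor distance, overall density), and 10 supervised
#' (large-cell ratio, three small/large intensity-PDF similarities, small
#' and large cell densities, and four small/large nearest-neighbor
#' distances).
#'
#' @param family `"all"`, `"unsupervised"`, `"mixed"`, or `"supervised"`.
#' @return a character vector of feature names.
#' @export
feature_names <- function(family = c("all", "unsupervised", "mixed",
                                     "supervised")) {
  family <- match.arg(family)
  unsup <- c("cll_like_ratio", "acll_like_ratio", "rt_like_ratio",
             "cll_like_density", "acll_like_density", "rt_like_density")
  mixed <- c("mean_cell_size", "mean_cell_intensity", "mean_nn_dist",
             "cell_density")
  sup <- c("large_cell_ratio", "sl_intensity_corr", "sl_intensity_chisq",
           "sl_intensity_wasserstein", "small_cell_density",
           "large_cell_density", "s2s_nn_dist", "s2l_nn_dist",
           "l2s_nn_dist", "l2l_nn_dist")
  switch(family, all = c(unsup, mixed, sup), unsupervised = unsup,
         mixed = mixed, supervised = sup)
}

#' Unsupervised features: phenotype ratios and densities
#'
#' For each phenotype, its cell ratio (count over total) and density
#' (count per mm^2 of ROI rectangle). A zero-cell ROI yields all six
#' features missing.
#'
#' @param tab a phenotype-labeled [cell_table()] (see
#'   [propagate_labels()]).
#' @return a named numeric vector of length 6.
#' @export
unsupervised_features <- function(tab) {
  out <- stats::setNames(rep(NA_real_, 6), feature_names("unsupervised"))
  n <- nrow(tab)
  if (n == 0) return(out)
  if (!"phenotype" %in% names(tab))
    stop("cell table has no phenotype labels; run propagate_labels() first",
         call. = FALSE)
  counts <- vapply(phenotype_names(), function(ph) sum(tab$phenotype == ph),
                   numeric(1))
  area <- roi_area_mm2(tab)
  out[1:3] <- counts / n
  out[4:6] <- counts / area
  out
}

#' Mixed features: whole-population morphometrics
#'
#' Mean nuclear area (um^2), mean intensity, mean distance from each
#' cell to its nearest neighbor (um; needs >= 2 cells), and overall
#' density (cells per mm^2).
#'
#' @param tab a [cell_table()].
#' @return a named numeric vector of length 4; undefined entries are
#'   `NA`.
#' @export
mixed_features <- function(tab) {
  out <- stats::setNames(rep(NA_real_, 4), feature_names("mixed"))
  n <- nrow(tab)
  if (n == 0) return(out)
  out["mean_cell_size"] <- mean(tab$area_um2)
  out["mean_cell_intensity"] <- mean(tab$mean_intensity)
  out["cell_density"] <- n / roi_area_mm2(tab)
  if (n >= 2) {
    pts <- cbind(tab$centroid_x_um, tab$centroid_y_um)
    out["mean_nn_dist"] <- mean(nn_min_dist(pts, pts, same_set = TRUE))
  }
  out
}

#' Mean nearest-neighbor distance between point sets
#'
#' Mean over source points of the Euclidean distance to the nearest
#' target point, excluding self-matches when `same_set = TRUE` (source
#' and target are then the same point set, in the same order).
#'
#' @param source_points,target_points 2-column matrices (x, y) in um.
#' @param same_set logical.
#' @return a scalar in um, or `NA` when the preconditions (>= 2 source
#'   points for `same_set`, otherwise >= 1 source and >= 1 target) fail.
#' @export
mean_nn_distance <- function(source_points, target_points,
                             same_set = FALSE) {
  ns <- nrow(source_points); nt <- nrow(target_points)
  if (same_set) {
    if (ns < 2) return(NA_real_)
  } else if (ns < 1 || nt < 1) return(NA_real_)
  mean(nn_min_dist(source_points, target_points, same_set = same_set))
}

#' Similarity between small- and large-cell intensity PDFs
#'
#' Both groups' intensities are binned into 32 uniform bins on
#' `[0, 256)` and normalized to empirical PDFs. Returns the Pearson
#' correlation of the binned PDFs, the symmetric chi-square statistic
#' `sum (p - q)^2 / (p + q)` over bins with `p + q > 0`, and the 1-D
#' Wasserstein distance between the raw (unbinned) intensity samples.
#'
#' @param small_intensities,large_intensities numeric vectors of gray
#'   levels in `[0, 255]`.
#' @param n_bins number of histogram bins (default 32).
#' @return named vector `c(sl_intensity_corr, sl_intensity_chisq,
#'   sl_intensity_wasserstein)`; all `NA` when either group is empty;
#'   correlation alone `NA` when a binned PDF has zero variance.
#' @export
intensity_pdf_similarity <- function(small_intensities, large_intensities,
                                     n_bins = 32L) {
  out <- stats::setNames(rep(NA_real_, 3),
                         c("sl_intensity_corr", "sl_intensity_chisq",
                           "sl_intensity_wasserstein"))
  if (length(small_intensities) == 0 || length(large_intensities) == 0)
    return(out)
  breaks <- seq(0, 256, length.out = n_bins + 1L)
  bin_pdf <- function(v) {
    cnt <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                    nbins = n_bins)
    cnt / sum(cnt)
  }
  p <- bin_pdf(small_intensities)
  q <- bin_pdf(large_intensities)
  if (stats::sd(p) > 0 && stats::sd(q) > 0)
    out["sl_intensity_corr"] <- stats::cor(p, q)
  nz <- (p + q) > 0
  out["sl_intensity_chisq"] <- sum((p[nz] - q[nz])^2 / (p[nz] + q[nz]))
  out["sl_intensity_wasserstein"] <-
    wasserstein1d(small_intensities, large_intensities)
  out
}

#' Supervised features: small/large-cell profile around a size cutoff
#'
#' Cells with area strictly greater than `cutoff_um2` are "large" (L),
#' the rest "small" (S). Features: large-cell ratio, the three S/L
#' intensity-PDF similarities, S and L densities (per mm^2), and the
#' mean S-to-S, S-to-L, L-to-S, and L-to-L nearest-neighbor distances
#' (um). Features whose group preconditions fail are `NA` (missing, not
#' zero -- the downstream boosted trees route missing values natively).
#'
#' @param tab a [cell_table()].
#' @param cutoff_um2 size cutoff in um^2 (see [optimize_size_cutoff()]).
#' @return a named numeric vector of length 10.
#' @export
supervised_features <- function(tab, cutoff_um2) {
  assert_scalar_number(cutoff_um2, "cutoff_um2")
  out <- stats::setNames(rep(NA_real_, 10), feature_names("supervised"))
  n <- nrow(tab)
  if (n == 0) return(out)
  large <- tab$area_um2 > cutoff_um2
  out["large_cell_ratio"] <- sum(large) / n
  out[c("sl_intensity_corr", "sl_intensity_chisq",
        "sl_intensity_wasserstein")] <-
    intensity_pdf_similarity(tab$mean_intensity[!large],
                             tab$mean_intensity[large])
  area <- roi_area_mm2(tab)
  out["small_cell_density"] <- sum(!large) / area
  out["large_cell_density"] <- sum(large) / area
  s_pts <- cbind(tab$centroid_x_um, tab$centroid_y_um)[!large, , drop = FALSE]
  l_pts <- cbind(tab$centroid_x_um, tab$centroid_y_um)[large, , drop = FALSE]
  out["s2s_nn_dist"] <- mean_nn_distance(s_pts, s_pts, same_set = TRUE)
  out["s2l_nn_dist"] <- mean_nn_distance(s_pts, l_pts)
  out["l2s_nn_dist"] <- mean_nn_distance(l_pts, s_pts)
  out["l2l_nn_dist"] <- mean_nn_distance(l_pts, l_pts, same_set = TRUE)
  out
}

#' Optimize the small/large size cutoff on training ROIs
#'
#' For each candidate cutoff `c` on an integer-um^2 grid from 8 to 108,
#' computes each training ROI's large-cell ratio `#(area > c) / n`,
#' averages it per disease class (`R_CLL`, `R_aCLL`, `R_RT`), and
#' evaluates the separation objective
#' `(R_RT - R_aCLL) * (R_aCLL - R_CLL) * (R_RT - R_CLL)`. Returns the
#' grid argmax, breaking ties toward the smallest cutoff.
#'
#' @param tables list of QC-passed [cell_table()]s with disease labels
#'   (each class represented by >= 1 ROI).
#' @param grid candidate cutoffs in um^2.
#' @return an object of class `cutoff_search`: `optimal_cutoff_um2`,
#'   `objective`, `class_ratios` (at the optimum), and `curve` (a
#'   data.frame cutoff/objective/R_CLL/R_aCLL/R_RT).
#' @export
optimize_size_cutoff <- function(tables, grid = seq(8, 108, by = 1)) {
  labels <- vapply(tables, function(tb) attr(tb, "disease_label"),
                   character(1))
  for (cls in disease_classes())
    if (!any(labels == cls))
      stop("no training ROIs for class ", cls, call. = FALSE)
  keep <- vapply(tables, nrow, 1L) > 0
  tables <- tables[keep]; labels <- labels[keep]
  # per-ROI large-cell ratio for every cutoff at once
  ratios <- vapply(tables, function(tb) {
    vapply(grid, function(cth) mean(tb$area_um2 > cth), numeric(1))
  }, numeric(length(grid)))  # grid x roi
  r_cls <- vapply(disease_classes(), function(cls)
    rowMeans(ratios[, labels == cls, drop = FALSE]),
    numeric(length(grid)))  # grid x 3
  obj <- (r_cls[, "RT"] - r_cls[, "aCLL"]) *
    (r_cls[, "aCLL"] - r_cls[, "CLL"]) *
    (r_cls[, "RT"] - r_cls[, "CLL"])
  best <- which.max(obj)  # first max = smallest cutoff on ties
  structure(list(
    optimal_cutoff_um2 = grid[best],
    objective = obj[best],
    class_ratios = c(R_CLL = unname(r_cls[best, "CLL"]),
                     R_aCLL = unname(r_cls[best, "aCLL"]),
                     R_RT = unname(r_cls[best, "RT"])),
    curve = data.frame(cutoff_um2 = grid, objective = obj,
                       R_CLL = r_cls[, "CLL"], R_aCLL = r_cls[, "aCLL"],
                       R_RT = r_cls[, "RT"])),
    class = "cutoff_search")
}

#' @export
print.cutoff_search <- function(x, ...) {
  cat(sprintf("<cutoff_search> optimal cutoff %.1f um^2, objective %.4g\n",
              x$optimal_cutoff_um2, x$objective))
  cat(sprintf("class mean large-cell ratios: CLL %.3f, aCLL %.3f, RT %.3f\n",
              x$class_ratios["R_CLL"], x$class_ratios["R_aCLL"],
              x$class_ratios["R_RT"]))
  invisible(x)
}

#' Compute the full 20-feature vector for one ROI
#'
#' Concatenates the unsupervised (6), mixed (4), and supervised (10)
#' families in canonical order. An empty ROI yields 20 missing values
#' with the ROI id preserved.
#'
#' @param tab a phenotype-labeled, QC-passed [cell_table()].
#' @param cutoff_um2 small/large size cutoff in um^2.
#' @return a one-row data.frame: `roi_id`, `label`, then the 20 features.
#' @export
featurize_roi <- function(tab, cutoff_um2) {
  feats <- c(unsupervised_features(tab), mixed_features(tab),
             supervised_features(tab, cutoff_um2))
  cbind(data.frame(roi_id = attr(tab, "roi_id"),
                   label = attr(tab, "disease_label"),
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(feats)))
}

#' Featurize every ROI of a cohort
#'
#' @param tables named list of phenotype-labeled, QC-passed
#'   [cell_table()]s.
#' @param cutoff_um2 size cutoff in um^2.
#' @param manifest optional [cohort_manifest()]; when given, a
#'   `patient_id` column is added and ROI labels are taken from the
#'   manifest.
#' @return a data.frame with one row per ROI: `roi_id`, (`patient_id`,)
#'   `label`, and the 20 feature columns.
#' @export
featurize_cohort <- function(tables, cutoff_um2, manifest = NULL) {
  rows <- lapply(tables, featurize_roi, cutoff_um2 = cutoff_um2)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(manifest)) {
    rois <- manifest_rois(manifest)
    m <- match(out$roi_id, rois$roi_id)
    out$patient_id <- rois$patient_id[m]
    out$label <- rois$class[m]
    out <- out[, c("roi_id", "patient_id", "label", feature_names("all"))]
  }
  out
}

#' Write a feature matrix as CSV (missing values as empty fields)
#'
#' @param features a [featurize_cohort()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
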