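#' Phenotype archetype parameters for the synthetic generator
#'
#' Each of the three cell phenotypes is parameterized by a lognormal
#' nuclear-size distribution (truncated to the 8-108 um^2 QC window), a
#' truncated-normal mean-intensity distribution on `[0, 255]`, and a beta
#' solidity distribution rescaled to `[0.7, 1]`.
#'
#' @param name phenotype name, one of [phenotype_names()].
#' @param size_mean_um2 median nuclear area in um^2 (lognormal scale).
#' @param size_sigma lognormal shape (sdlog).
#' @param intensity_mean,intensity_sd normal parameters for mean gray
#'   level (0-255).
#' @param solidity_a,solidity_b beta shape parameters; samples are mapped
#'   to `0.7 + 0.3 * Beta(a, b)`.
#' @param size_range optional extra truncation of the size support (um^2),
#'   intersected with the 8-108 window; used to build benchmark cohorts
#'   with a hard small/large size gap.
#' @return a list of class `phenotype_params`.
#' @export
phenotype_params <- function(name, size_mean_um2, size_sigma,
                             intensity_mean, intensity_sd,
                             solidity_a = 14, solidity_b = 2,
                             size_range = c(8, 108)) {
  if (!name %in% phenotype_names())
    stop("unknown phenotype name: ", name, call. = FALSE)
  stopifnot(length(size_range) == 2, size_range[1] < size_range[2])
  structure(list(name = name, size_mean_um2 = size_mean_um2,
                 size_sigma = size_sigma, intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd, solidity_a = solidity_a,
                 solidity_b = solidity_b,
                 size_range = c(max(8, size_range[1]),
                                min(108, size_range[2]))),
            class = "phenotype_params")
}

#' Default phenotype archetypes
#'
#' CLL-like cells are small and dim (median 14 um^2, gray level 110),
#' aCLL-like cells are small but brighter (16 um^2, 160), and RT-like
#' cells are large (45 um^2, 130) -- the qualitative size/intensity
#' ordering that separates the three disease-stage phenotypes, with the
#' small/large boundary falling in the low-20s um^2 range. Fully
#' configurable; these are simulation fixtures, not measured values.
#'
#' @return a named list of three [phenotype_params()].
#' @export
default_phenotype_params <- function() {
  list(
    "CLL-like"  = phenotype_params("CLL-like",  14, 0.18, 110, 10),
    "aCLL-like" = phenotype_params("aCLL-like", 16, 0.18, 160, 10),
    "RT-like"   = phenotype_params("RT-like",   45, 0.25, 130, 12)
  )
}

#' Well-separated benchmark archetypes with a hard size gap
#'
#' A benchmark parameterization for recovery experiments: the two small
#' phenotypes share one size distribution (median 15 um^2, support
#' truncated to 8-22 um^2) and are separated by intensity alone (108 vs
#' 162 gray levels, SD 9), while RT-like nuclei are large with support
#' 28-108 um^2. The size supports leave a generating small/large gap of
#' `[22, 28]` um^2, so the supervised cutoff search has a well-defined
#' target, and all pairwise archetype separations exceed five within-
#' phenotype SDs, so clustering should recover the generating labels
#' nearly perfectly.
#'
#' @return a named list of three [phenotype_params()]; the `size_gap`
#'   attribute holds the generating gap `c(22, 28)`.
#' @export
separated_phenotype_params <- function() {
  structure(list(
    "CLL-like"  = phenotype_params("CLL-like",  15, 0.18, 108, 9,
                                   size_range = c(8, 22)),
    "aCLL-like" = phenotype_params("aCLL-like", 15, 0.18, 162, 9,
                                   size_range = c(8, 22)),
    "RT-like"   = phenotype_params("RT-like",   45, 0.25, 135, 9,
                                   size_range = c(28, 108))
  ), size_gap = c(22, 28))
}

#' Disease-class phenotype mixtures
#'
#' The proportion of each cell phenotype within ROIs of each disease
#' class. Defaults encode the enrichment pattern across disease stages:
#' the RT-like fraction increases monotonically from CLL to aCLL to RT
#' while the CLL-like fraction decreases. `null_class_mixtures()` gives
#' identical uniform mixtures (no class signal), for null-behavior
#' checks.
#'
#' @return a named list of 3-vectors (one per disease class), each
#'   summing to 1 over `c("CLL-like", "aCLL-like", "RT-like")`.
#' @export
default_class_mixtures <- function() {
  list(CLL  = c("CLL-like" = 0.80, "aCLL-like" = 0.15, "RT-like" = 0.05),
       aCLL = c("CLL-like" = 0.25, "aCLL-like" = 0.60, "RT-like" = 0.15),
       RT   = c("CLL-like" = 0.10, "aCLL-like" = 0.25, "RT-like" = 0.65))
}

#' @rdname default_class_mixtures
#' @export
null_class_mixtures <- function() {
  u <- stats::setNames(rep(1 / 3, 3), phenotype_names())
  list(CLL = u, aCLL = u, RT = u)
}

#' Benchmark cohort with well-separated archetypes
#'
#' A 60-patient synthetic cohort (20 per class) generated with the
#' [separated_phenotype_params()] archetypes and the default class
#' mixtures: the standard recovery benchmark on which clustering should
#' recover the generating phenotypes, propagated ratios should match
#' the configured mixtures, and the supervised cutoff search should land
#' in the generating size gap.
#'
#' @param seed master seed.
#' @param patients_per_class patients per disease class.
#' @param ... further arguments to [cohort_config()].
#' @return a `synthetic_cohort` (see [generate_cohort()]).
#' @export
benchmark_cohort <- function(seed = 1L, patients_per_class = 20, ...) {
  generate_cohort(cohort_config(patients_per_class = patients_per_class,
                                seed = seed, ...),
                  params = separated_phenotype_params())
}

#' @noRd
check_mixture <- function(mix) {
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-12)
    stop("mixture proportions must be >= 0 and sum to 1", call. = FALSE)
  invisible(mix)
}

#' Synthetic cohort configuration
#'
#' @param patients_per_class number of patients in each disease class.
#' @param slides_per_patient integer range `c(lo, hi)`.
#' @param rois_per_slide integer range `c(lo, hi)` (default 1-8 ROIs, the
#'   range seen on clinical slides).
#' @param cells_per_roi integer range `c(lo, hi)`.
#' @param roi_width_px,roi_height_px ROI dimensions in pixels (>= 512).
#' @param resolution micrometres per pixel (default 0.50).
#' @param contaminant_fraction fraction of cells drawn as segmentation
#'   artifacts -- solidity below 0.84 or area outside the 8-108 um^2
#'   window -- to exercise the QC filter (default 0.02, i.e. ~98% of
#'   nuclei survive filtering).
#' @param seed master integer seed; per-ROI seeds are derived by stable
#'   hashing of (seed, patient, slide, roi).
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(patients_per_class = 20,
                          slides_per_patient = c(1, 2),
                          rois_per_slide = c(1, 8),
                          cells_per_roi = c(200, 500),
                          roi_width_px = 768, roi_height_px = 768,
                          resolution = 0.5,
                          contaminant_fraction = 0.02,
                          seed = 1L) {
  stopifnot(patients_per_class >= 1,
            length(slides_per_patient) == 2, length(rois_per_slide) == 2,
            length(cells_per_roi) == 2)
  if (roi_width_px < 512 || roi_height_px < 512)
    stop("ROI dimensions must be >= 512 px", call. = FALSE)
  if (contaminant_fraction < 0 || contaminant_fraction >= 1)
    stop("contaminant_fraction must be in [0, 1)", call. = FALSE)
  assert_scalar_number(resolution, "resolution", positive = TRUE)
  structure(list(patients_per_class = patients_per_class,
                 slides_per_patient = slides_per_patient,
                 rois_per_slide = rois_per_slide,
                 cells_per_roi = cells_per_roi,
                 roi_width_px = roi_width_px,
                 roi_height_px = roi_height_px,
                 resolution = resolution,
                 contaminant_fraction = contaminant_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Truncated sampling via the inverse CDF (exact, no rejection loop).
#' @noRd
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' @noRd
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate the cells of one synthetic ROI
#'
#' Per-cell phenotypes are drawn from the class mixture, attributes from
#' the phenotype archetypes, and centroids uniformly over the ROI
#' rectangle. A `contaminant_fraction` of cells is redrawn as
#' segmentation artifacts (solidity in `[0.5, 0.84)` or pixel area
#' outside 32-432 px) so the QC filter has something to remove. The
#' ground-truth phenotype is stored in the `truth_phenotype` column and
#' the artifact flag in `contaminant`.
#'
#' @param disease_class one of [disease_classes()].
#' @param n_cells number of cells (>= 0).
#' @param mixtures named list of class mixtures, see
#'   [default_class_mixtures()].
#' @param params named list of phenotype archetypes, see
#'   [default_phenotype_params()].
#' @param roi_width_px,roi_height_px ROI dimensions in pixels.
#' @param resolution micrometres per pixel.
#' @param seed integer seed; identical arguments and seed give identical
#'   tables.
#' @param contaminant_fraction see [cohort_config()].
#' @param roi_id,disease_label ROI metadata.
#' @return a [cell_table()] with `truth_phenotype` and `contaminant`
#'   columns.
#' @export
generate_roi_cells <- function(disease_class, n_cells,
                               mixtures = default_class_mixtures(),
                               params = default_phenotype_params(),
                               roi_width_px = 768, roi_height_px = 768,
                               resolution = 0.5, seed = 1L,
                               contaminant_fraction = 0,
                               roi_id = paste0(disease_class, "-roi"),
                               disease_label = disease_class) {
  if (!disease_class %in% names(mixtures))
    stop("no mixture configured for disease class: ", disease_class,
         call. = FALSE)
  mix <- check_mixture(mixtures[[disease_class]])
  stopifnot(n_cells >= 0)
  area_window_px <- c(32L, 432L) * (0.5 / resolution)^2
  with_seed(seed, {
    pheno <- if (n_cells > 0)
      sample(phenotype_names(), n_cells, replace = TRUE, prob = mix)
    else character(0)
    area_um2 <- numeric(n_cells)
    intensity <- numeric(n_cells)
    solidity <- numeric(n_cells)
    for (ph in phenotype_names()) {
      idx <- which(pheno == ph)
      if (length(idx) == 0) next
      p <- params[[ph]]
      rng <- p$size_range %||% c(8, 108)
      area_um2[idx] <- rlnorm_trunc(length(idx), log(p$size_mean_um2),
                                    p$size_sigma, rng[1], rng[2])
      intensity[idx] <- rnorm_trunc(length(idx), p$intensity_mean,
                                    p$intensity_sd, 0, 255)
      solidity[idx] <- 0.7 + 0.3 * stats::rbeta(length(idx),
                                                p$solidity_a, p$solidity_b)
    }
    area_px <- pmin(pmax(round(area_um2 / resolution^2),
                         ceiling(area_window_px[1])),
                    floor(area_window_px[2]))
    contaminant <- stats::runif(n_cells) < contaminant_fraction
    if (any(contaminant)) {
      idx <- which(contaminant)
      kind <- sample(c("solidity", "small", "large"), length(idx),
                     replace = TRUE)
      s_idx <- idx[kind == "solidity"]
      solidity[s_idx] <- stats::runif(length(s_idx), 0.5, 0.8399)
      sm_idx <- idx[kind == "small"]
      area_px[sm_idx] <- sample(seq.int(8, ceiling(area_window_px[1]) - 1),
                                length(sm_idx), replace = TRUE)
      lg_idx <- idx[kind == "large"]
      area_px[lg_idx] <- sample(seq.int(floor(area_window_px[2]) + 1, 700),
                                length(lg_idx), replace = TRUE)
    }
    cx <- stats::runif(n_cells, 0, roi_width_px * resolution)
    cy <- stats::runif(n_cells, 0, roi_height_px * resolution)
    cells <- data.frame(
      cell_id = if (n_cells > 0) sprintf("%s-c%05d", roi_id, seq_len(n_cells))
                else character(0),
      area_px = as.numeric(area_px),
      mean_intensity = intensity,
      centroid_x_um = cx,
      centroid_y_um = cy,
      solidity = solidity,
      truth_phenotype = pheno,
      contaminant = contaminant,
      stringsAsFactors = FALSE)
    cell_table(cells, roi_id = roi_id, resolution = resolution,
               roi_width_px = roi_width_px, roi_height_px = roi_height_px,
               disease_label = disease_label)
  })
}

#' Generate a full synthetic cohort
#'
#' Builds the patient -> slide -> ROI hierarchy, samples binary patient
#' covariates (gender, age group, slide source, biopsy technique, overall
#' survival group) with class-independent marginals resembling a mixed
#' clinical cohort, and generates each ROI's cell table with a seed
#' derived from (master seed, patient, slide, roi), so any ROI can be
#' regenerated in isolation.
#'
#' @param config a [cohort_config()].
#' @param mixtures,params see [generate_roi_cells()].
#' @return a list of class `synthetic_cohort` with elements `manifest`
#'   (a [cohort_manifest()]), `cells` (named list of [cell_table()] by
#'   ROI id), `mixtures`, `params`, and `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            mixtures = default_class_mixtures(),
                            params = default_phenotype_params()) {
  stopifnot(inherits(config, "cohort_config"))
  lapply(mixtures, check_mixture)
  covariate_p <- c(gender_male = 0.63, age_ge60 = 0.48, source_inhouse = 0.54,
                   biopsy_cnb = 0.59, os_shorter = 0.59)
  hierarchy <- with_seed(derive_seed(config$seed, "manifest"), {
    patients <- list()
    for (cls in disease_classes()) {
      for (i in seq_len(config$patients_per_class)) {
        pid <- sprintf("%s-P%03d", cls, i)
        cov <- as.list(stats::runif(length(covariate_p)) < covariate_p)
        names(cov) <- names(covariate_p)
        n_slides <- sample_range(config$slides_per_patient)
        slides <- lapply(seq_len(n_slides), function(s) {
          sid <- sprintf("%s-S%d", pid, s)
          n_rois <- sample_range(config$rois_per_slide)
          rois <- sprintf("%s-R%d", sid, seq_len(n_rois))
          n_cells <- sample_range(config$cells_per_roi, n_rois)
          list(id = sid, rois = rois, n_cells = as.list(n_cells))
        })
        patients[[length(patients) + 1L]] <-
          list(id = pid, class = cls, covariates = cov, slides = slides)
      }
    }
    patients
  })
  cells <- list()
  for (p in hierarchy) {
    for (s in seq_along(p$slides)) {
      sl <- p$slides[[s]]
      for (r in seq_along(sl$rois)) {
        roi_id <- sl$rois[r]
        cells[[roi_id]] <- generate_roi_cells(
          p$class, n_cells = sl$n_cells[[r]], mixtures = mixtures,
          params = params, roi_width_px = config$roi_width_px,
          roi_height_px = config$roi_height_px,
          resolution = config$resolution,
          seed = derive_seed(config$seed, p$id, sl$id, roi_id),
          contaminant_fraction = config$contaminant_fraction,
          roi_id = roi_id, disease_label = p$class)
      }
    }
  }
  manifest_patients <- lapply(hierarchy, function(p) {
    p$slides <- lapply(p$slides, function(s) list(id = s$id, rois = s$rois))
    p
  })
  structure(list(manifest = cohort_manifest(manifest_patients),
                 cells = cells, mixtures = mixtures, params = params,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  print(x$manifest)
  cat(sprintf("total cells: %d\n",
              sum(vapply(x$cells, nrow, 1L))))
  invisible(x)
}

#' Render a cell table as an instance label mask and grayscale image
#'
#' Cells are drawn as non-overlapping ellipse-shaped pixel blobs of
#' exactly `area_px` pixels each (the `area_px` pixels closest to the
#' center in the ellipse metric), centered at the cell centroid; on
#' overlap, a fresh seeded center is drawn up to `max_attempts` times and
#' unplaceable cells are reported. Mask labels are `1..n_placed`
#' (background 0); the grayscale image fills each nucleus with its
#' rounded mean intensity.
#'
#' @param tab a [cell_table()].
#' @param max_attempts placement attempts per cell before giving up.
#' @param seed integer seed for replacement draws and ellipse shapes.
#' @return a list with `mask` (integer matrix, rows = y), `image`
#'   (integer matrix, 0-255), and `placed` (indices of `tab` rows that
#'   were placed; the mask label of `placed[i]` is `i`).
#' @export
render_label_mask <- function(tab, max_attempts = 50L, seed = 1L) {
  meta <- roi_meta(tab)
  w <- round(meta$roi_width_um / meta$resolution)
  h <- round(meta$roi_height_um / meta$resolution)
  mask <- matrix(0L, nrow = h, ncol = w)
  image <- matrix(0L, nrow = h, ncol = w)
  placed <- integer(0)
  if (nrow(tab) == 0) return(list(mask = mask, image = image, placed = placed))
  with_seed(seed, {
    label <- 0L
    for (i in seq_len(nrow(tab))) {
      a_px <- round(tab$area_px[i])
      aspect <- stats::runif(1, 1, 1.5)
      theta <- stats::runif(1, 0, pi)
      # semi-axes (px) of an ellipse with the target area
      sa <- sqrt(a_px * aspect / pi)
      sb <- sa / aspect
      cx0 <- tab$centroid_x_um[i] / meta$resolution
      cy0 <- tab$centroid_y_um[i] / meta$resolution
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        if (attempt == 1L) {
          cx <- cx0; cy <- cy0
        } else {
          cx <- stats::runif(1, sa, w - sa)
          cy <- stats::runif(1, sa, h - sa)
        }
        pix <- ellipse_pixels(cx, cy, sa, sb, theta, a_px, w, h)
        if (is.null(pix)) next
        if (all(mask[pix] == 0L)) {
          label <- label + 1L
          mask[pix] <- label
          image[pix] <- as.integer(round(tab$mean_intensity[i]))
          placed <- c(placed, i)
          ok <- TRUE
          break
        }
      }
    }
  })
  list(mask = mask, image = image, placed = placed)
}

# The a_px pixels nearest to (cx, cy) in the ellipse metric, as matrix
# indices (row = y + 1, col = x + 1); NULL if the ellipse does not fit.
#' @noRd
ellipse_pixels <- function(cx, cy, sa, sb, theta, a_px, w, h) {
  r <- ceiling(sa) + 2L
  xs <- seq.int(max(0L, floor(cx) - r), min(w - 1L, ceiling(cx) + r))
  ys <- seq.int(max(0L, floor(cy) - r), min(h - 1L, ceiling(cy) + r))
  if (length(xs) * length(ys) < a_px) return(NULL)
  gx <- rep(xs, times = length(ys)) - cx
  gy <- rep(ys, each = length(xs)) - cy
  u <- (gx * cos(theta) + gy * sin(theta)) / sa
  v <- (-gx * sin(theta) + gy * cos(theta)) / sb
  m <- u * u + v * v
  ord <- order(m)[seq_len(a_px)]
  px <- rep(xs, times = length(ys))[ord]
  py <- rep(ys, each = length(xs))[ord]
  # reject if the blob would spill past the window (ellipse clipped)
  if (max(m[ord]) > 4) return(NULL)
  cbind(py + 1L, px + 1L)
}

#' Write and read instance label masks and grayscale images
#'
#' Masks are stored as single-channel 16-bit TIFF (labels 0-65535);
#' grayscale images as 8-bit PNG or TIFF depending on the file
#' extension.
#'
#' @param mask,image integer matrices as produced by
#'   [render_label_mask()].
#' @param path output path (`.tif`/`.tiff` for masks; `.png` or `.tif`
#'   for images).
#' @return the path, invisibly; readers return an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(max(mask) <= 65535)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' @rdname write_label_mask
#' @export
write_grayscale_image <- function(image, path) {
  stopifnot(max(image) <= 255, min(image) >= 0)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(image / 255, path)
  } else {
    tiff::writeTIFF(image / 255, path, bits.per.sample = 8)
  }
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_grayscale_image <- function(path) {
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    round(png::readPNG(path) * 255)
  } else {
    g <- tiff::readTIFF(path, as.is = TRUE)
    if (max(g) <= 1) round(g * 255) else g
  }
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

#' Write a synthetic cohort to a directory
#'
#' Writes `manifest.json`, one cell-table CSV per ROI under `cells/`, and
#' (optionally) instance masks and grayscale images under `masks/` and
#' `images/`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param masks also render and write label masks (slow; default FALSE).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, masks = FALSE) {
  dir.create(file.path(dir, "cells"), recursive = TRUE, showWarnings = FALSE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.json"))
  for (roi_id in names(cohort$cells)) {
    write_cell_table(cohort$cells[[roi_id]],
                     file.path(dir, "cells", paste0(roi_id, ".csv")))
  }
  if (masks) {
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    for (roi_id in names(cohort$cells)) {
      r <- render_label_mask(cohort$cells[[roi_id]],
                             seed = derive_seed(cohort$config$seed, "mask",
                                                roi_id))
      write_label_mask(r$mask, file.path(dir, "masks",
                                         paste0(roi_id, ".tif")))
      write_grayscale_image(r$image, file.path(dir, "images",
                                               paste0(roi_id, ".png")))
    }
  }
  invisible(dir)
}
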