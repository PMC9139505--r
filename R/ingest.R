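#' Extract per-nucleus attributes from an instance label mask
#'
#' Given an integer-labeled instance mask (background 0) and a matching
#' grayscale intensity image, computes one cell per positive label:
#' pixel area, mean intensity over the label's pixels, the unweighted
#' pixel centroid converted to micrometres (0-based indices, x = column,
#' y = row), and solidity as pixel area divided by the pixel area of the
#' region's convex hull (pixels whose centers fall inside or on the hull
#' of the region's pixel centers).
#'
#' @param label_mask integer matrix; rows index y, columns x.
#' @param intensity_image numeric/integer matrix of the same dimensions,
#'   gray levels 0-255.
#' @param resolution micrometres per pixel.
#' @param roi_id,disease_label ROI metadata for the resulting table.
#' @return a [cell_table()] with one row per positive label, in label
#'   order.
#' @export
cells_from_mask <- function(label_mask, intensity_image, resolution = 0.5,
                            roi_id = "roi", disease_label = NA_character_) {
  if (!all(dim(label_mask) == dim(intensity_image)))
    stop("mask and intensity image dimensions differ", call. = FALSE)
  if (any(label_mask != round(label_mask)))
    stop("label mask must be integer-valued", call. = FALSE)
  labels <- sort(unique(label_mask[label_mask > 0]))
  h <- nrow(label_mask); w <- ncol(label_mask)
  n <- length(labels)
  area_px <- integer(n); inten <- numeric(n)
  cx <- numeric(n); cy <- numeric(n); sol <- numeric(n)
  idx_all <- which(label_mask > 0)
  lab_of <- label_mask[idx_all]
  # 0-based pixel coordinates: x = column, y = row
  px <- (idx_all - 1L) %/% h
  py <- (idx_all - 1L) %% h
  iv <- intensity_image[idx_all]
  for (j in seq_len(n)) {
    sel <- lab_of == labels[j]
    xs <- px[sel]; ys <- py[sel]
    area_px[j] <- sum(sel)
    inten[j] <- mean(iv[sel])
    cx[j] <- mean(xs) * resolution
    cy[j] <- mean(ys) * resolution
    sol[j] <- area_px[j] / convex_hull_pixel_count(xs, ys)
  }
  cells <- data.frame(cell_id = sprintf("%s-c%05d", roi_id, seq_len(n)),
                      area_px = as.numeric(area_px), mean_intensity = inten,
                      centroid_x_um = cx, centroid_y_um = cy,
                      solidity = pmin(sol, 1),
                      stringsAsFactors = FALSE)
  cell_table(cells, roi_id = roi_id, resolution = resolution,
             roi_width_px = w, roi_height_px = h,
             disease_label = disease_label, validate = FALSE)
}

# Number of pixel centers inside or on the convex hull of the given
# pixel centers. Half-plane test against each hull edge with a small
# tolerance; degenerate (collinear) regions return the pixel count
# itself, giving solidity 1.
#' @noRd
convex_hull_pixel_count <- function(xs, ys) {
  n <- length(xs)
  if (n <= 2L) return(n)
  hull <- grDevices::chull(xs, ys)
  if (length(hull) < 3L) return(n)
  hx <- xs[hull]; hy <- ys[hull]  # chull returns clockwise order
  hx <- rev(hx); hy <- rev(hy)    # counterclockwise
  gx <- seq.int(min(xs), max(xs))
  gy <- seq.int(min(ys), max(ys))
  qx <- rep(gx, times = length(gy))
  qy <- rep(gy, each = length(gx))
  inside <- rep(TRUE, length(qx))
  m <- length(hull)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    cross <- ex * (qy - hy[i]) - ey * (qx - hx[i])
    inside <- inside & (cross >= -1e-9)
  }
  sum(inside)
}

#' Quality-filter a cell table by solidity and nuclear size
#'
#' Retains cells with `solidity >= solidity_min` (low solidity flags
#' merged/overlapping segmented nuclei) and area inside the closed
#' window `area_window_um2` (8-108 um^2 by default, i.e. 32-432 px at
#' 0.50 um/px). Relative cell order is preserved and the filter is
#' idempotent.
#'
#' @param tab a [cell_table()].
#' @param solidity_min solidity cutoff; cells at exactly the cutoff are
#'   kept (default 0.84).
#' @param area_window_um2 closed area window `c(low, high)` in um^2.
#' @return the filtered [cell_table()], with a `filter_report` attribute:
#'   a list with counts `n_input`, `n_kept`, `removed_solidity`,
#'   `removed_size` (a cell failing both rules counts under solidity).
#' @export
filter_cells <- function(tab, solidity_min = 0.84,
                         area_window_um2 = c(8, 108)) {
  if (area_window_um2[1] > area_window_um2[2])
    stop("area window low must be <= high", call. = FALSE)
  ok_sol <- tab$solidity >= solidity_min
  ok_size <- tab$area_um2 >= area_window_um2[1] &
    tab$area_um2 <= area_window_um2[2]
  keep <- ok_sol & ok_size
  out <- rewrap_cell_table(tab[keep, , drop = FALSE], tab)
  attr(out, "filter_report") <- list(
    n_input = nrow(tab),
    n_kept = sum(keep),
    removed_solidity = sum(!ok_sol),
    removed_size = sum(ok_sol & !ok_size))
  out
}

#' @rdname filter_cells
#' @export
filter_report <- function(tab) attr(tab, "filter_report")
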