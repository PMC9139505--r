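#' Construct a per-ROI cell table
#'
#' The atomic input of the pipeline: one row per segmented nucleus in one
#' region of interest (ROI), with pixel area, mean grayscale intensity
#' (0-255), centroid (stored in micrometres from the ROI origin), and
#' solidity. ROI-level metadata (id, resolution, physical dimensions, and
#' an optional disease label) travels as attributes so that densities and
#' distances can be computed without side tables.
#'
#' @param cells a data.frame with columns `cell_id`, `area_px`,
#'   `mean_intensity`, `centroid_x_um`, `centroid_y_um`, `solidity`, and
#'   optionally `truth_phenotype` and/or `phenotype`.
#' @param roi_id character ROI identifier.
#' @param resolution micrometres per pixel (default 0.5).
#' @param roi_width_px,roi_height_px ROI dimensions in pixels.
#' @param disease_label optional disease class, one of
#'   [disease_classes()], or `NA`.
#' @param validate check invariants (default `TRUE`).
#' @return an object of class `cell_table` (a data.frame).
#' @export
cell_table <- function(cells, roi_id, resolution = 0.5,
                       roi_width_px, roi_height_px,
                       disease_label = NA_character_,
                       validate = TRUE) {
  assert_scalar_number(resolution, "resolution", positive = TRUE)
  required <- c("cell_id", "area_px", "mean_intensity",
                "centroid_x_um", "centroid_y_um", "solidity")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0)
    stop("cell table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cells <- as.data.frame(cells)
  cells$area_um2 <- pixel_area_to_um2(cells$area_px, resolution)
  rownames(cells) <- NULL
  structure(cells,
            class = c("cell_table", "data.frame"),
            roi_id = as.character(roi_id),
            resolution = resolution,
            roi_width_um = roi_width_px * resolution,
            roi_height_um = roi_height_px * resolution,
            disease_label = as.character(disease_label)) -> tab
  if (validate) validate_cell_table(tab)
  tab
}

#' @rdname cell_table
#' @param x an object.
#' @export
is_cell_table <- function(x) inherits(x, "cell_table")

#' @noRd
roi_meta <- function(tab) {
  list(roi_id = attr(tab, "roi_id"),
       resolution = attr(tab, "resolution"),
       roi_width_um = attr(tab, "roi_width_um"),
       roi_height_um = attr(tab, "roi_height_um"),
       disease_label = attr(tab, "disease_label"))
}

#' @noRd
roi_area_mm2 <- function(tab) {
  attr(tab, "roi_width_um") * attr(tab, "roi_height_um") / 1e6
}

# Rebuild a cell_table around a (possibly subset) cell data.frame, keeping
# the donor's ROI metadata.
#' @noRd
rewrap_cell_table <- function(cells, donor) {
  meta <- roi_meta(donor)
  rownames(cells) <- NULL
  structure(as.data.frame(cells),
            class = c("cell_table", "data.frame"),
            roi_id = meta$roi_id,
            resolution = meta$resolution,
            roi_width_um = meta$roi_width_um,
            roi_height_um = meta$roi_height_um,
            disease_label = meta$disease_label)
}

#' Validate a cell table against its invariants
#'
#' Checks intensity in `[0, 255]`, solidity in `(0, 1]`, positive pixel
#' areas, centroids inside the ROI rectangle, and the minimum ROI width of
#' 512 pixels. Offending row indices are listed in the error.
#'
#' @param tab a [cell_table()].
#' @return `tab`, invisibly.
#' @export
validate_cell_table <- function(tab) {
  meta <- roi_meta(tab)
  if (meta$roi_width_um < 512 * meta$resolution - 1e-9 ||
      meta$roi_height_um < 512 * meta$resolution - 1e-9)
    stop("ROI must be at least 512 pixels in each dimension", call. = FALSE)
  if (nrow(tab) == 0) return(invisible(tab))
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0)
      stop(sprintf("invalid %s in row(s): %s", what,
                   paste(utils::head(rows, 10), collapse = ", ")),
           call. = FALSE)
  }
  bad(!is.finite(tab$area_px) | tab$area_px < 1, "area_px (< 1)")
  bad(!is.finite(tab$mean_intensity) | tab$mean_intensity < 0 |
        tab$mean_intensity > 255, "mean_intensity (outside [0, 255])")
  bad(!is.finite(tab$solidity) | tab$solidity <= 0 | tab$solidity > 1,
      "solidity (outside (0, 1])")
  bad(tab$centroid_x_um < 0 | tab$centroid_x_um > meta$roi_width_um |
        tab$centroid_y_um < 0 | tab$centroid_y_um > meta$roi_height_um,
      "centroid (outside ROI bounds)")
  invisible(tab)
}

#' @export
print.cell_table <- function(x, ...) {
  meta <- roi_meta(x)
  cat(sprintf("<cell_table> ROI %s: %d cells, %.0f x %.0f um (%.2f um/px)",
              meta$roi_id, nrow(x), meta$roi_width_um, meta$roi_height_um,
              meta$resolution))
  if (!is.na(meta$disease_label))
    cat(", label", meta$disease_label)
  cat("\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more rows\n")
  invisible(x)
}

#' Convert a pixel area to square micrometres
#'
#' At the scanner resolution used throughout (0.50 um/pixel by default),
#' 32 px corresponds to 8 um^2 and 432 px to 108 um^2 -- the retained
#' nuclear size window.
#'
#' @param area_px pixel count(s), `>= 0`.
#' @param resolution_um_per_px micrometres per pixel, `> 0`.
#' @return `area_px * resolution^2`, in um^2.
#' @export
#' @examples
#' pixel_area_to_um2(c(32, 432), 0.5)  # 8, 108
pixel_area_to_um2 <- function(area_px, resolution_um_per_px) {
  assert_scalar_number(resolution_um_per_px, "resolution_um_per_px",
                       positive = TRUE)
  if (any(area_px < 0, na.rm = TRUE))
    stop("`area_px` must be >= 0", call. = FALSE)
  area_px * resolution_um_per_px^2
}

# ---- CSV round trip -------------------------------------------------------

# The on-disk schema stores centroids in pixels; ROI metadata goes in a
# single '#'-prefixed header line so one file is self-describing.
csv_columns <- c("roi_id", "cell_id", "area_px", "mean_intensity",
                 "centroid_x_px", "centroid_y_px", "solidity")

#' Read and write per-ROI cell tables as CSV
#'
#' The CSV schema has columns `roi_id`, `cell_id`, `area_px`,
#' `mean_intensity`, `centroid_x_px`, `centroid_y_px`, `solidity`, and
#' optionally `truth_phenotype` / `phenotype`. ROI metadata (resolution,
#' dimensions, disease label) is written as a `#`-prefixed key=value
#' header line and restored on read; if the header is absent the metadata
#' must be supplied.
#'
#' @param tab a [cell_table()].
#' @param path file path.
#' @param resolution,roi_width_px,roi_height_px,disease_label metadata
#'   overrides used when the file has no metadata header.
#' @return `write_cell_table` returns `path` invisibly; `read_cell_table`
#'   returns a [cell_table()]. Rows violating the intensity or solidity
#'   invariants raise a validation error listing the rows.
#' @export
write_cell_table <- function(tab, path) {
  meta <- roi_meta(tab)
  out <- data.frame(
    roi_id = rep(meta$roi_id, nrow(tab)),
    cell_id = tab$cell_id,
    area_px = tab$area_px,
    mean_intensity = tab$mean_intensity,
    centroid_x_px = tab$centroid_x_um / meta$resolution,
    centroid_y_px = tab$centroid_y_um / meta$resolution,
    solidity = tab$solidity,
    stringsAsFactors = FALSE)
  for (extra in c("truth_phenotype", "phenotype"))
    if (extra %in% names(tab)) out[[extra]] <- tab[[extra]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# resolution=%.17g roi_width_px=%.17g roi_height_px=%.17g disease_label=%s",
    meta$resolution, meta$roi_width_um / meta$resolution,
    meta$roi_height_um / meta$resolution,
    ifelse(is.na(meta$disease_label), "NA", meta$disease_label)), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path, resolution = NULL, roi_width_px = NULL,
                            roi_height_px = NULL, disease_label = NULL) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#")) {
    kv <- strsplit(trimws(sub("^#", "", first)), "[ =]+")[[1]]
    meta <- stats::setNames(kv[seq(2, length(kv), 2)],
                            kv[seq(1, length(kv), 2)])
    resolution <- resolution %||% as.numeric(meta[["resolution"]])
    roi_width_px <- roi_width_px %||% as.numeric(meta[["roi_width_px"]])
    roi_height_px <- roi_height_px %||% as.numeric(meta[["roi_height_px"]])
    disease_label <- disease_label %||% meta[["disease_label"]]
    if (identical(disease_label, "NA")) disease_label <- NA_character_
  }
  if (is.null(resolution) || is.null(roi_width_px) || is.null(roi_height_px))
    stop("file has no metadata header; supply resolution and ROI dimensions",
         call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(csv_columns, names(df))
  if (length(missing_cols) > 0)
    stop("cell-table CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cells <- data.frame(
    cell_id = df$cell_id,
    area_px = df$area_px,
    mean_intensity = df$mean_intensity,
    centroid_x_um = df$centroid_x_px * resolution,
    centroid_y_um = df$centroid_y_px * resolution,
    solidity = df$solidity,
    stringsAsFactors = FALSE)
  for (extra in c("truth_phenotype", "phenotype"))
    if (extra %in% names(df)) cells[[extra]] <- df[[extra]]
  roi_id <- if (nrow(df) > 0) df$roi_id[1] else
    sub("\\.csv$", "", basename(path))
  cell_table(cells, roi_id = roi_id, resolution = resolution,
             roi_width_px = roi_width_px, roi_height_px = roi_height_px,
             disease_label = disease_label %||% NA_character_)
}
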