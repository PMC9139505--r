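#' Construct a cohort manifest
#'
#' The patient -> slide -> ROI hierarchy that drives patient-level
#' splitting. Each patient carries a disease class and binary clinical
#' covariates (gender, age group, slide source, biopsy technique, overall
#' survival group); each slide lists its ROI ids.
#'
#' @param patients a list; each element is a list with fields `id`,
#'   `class` (one of [disease_classes()]), `covariates` (named list of
#'   binary/character values), and `slides` (list of lists with `id` and
#'   `rois`, a character vector of ROI ids).
#' @return an object of class `cohort_manifest`.
#' @export
cohort_manifest <- function(patients) {
  m <- structure(list(patients = patients), class = "cohort_manifest")
  validate_manifest(m)
  m
}

#' @noRd
validate_manifest <- function(m) {
  rois <- manifest_rois(m)
  if (anyDuplicated(rois$roi_id))
    stop("duplicate ROI id(s): ",
         paste(unique(rois$roi_id[duplicated(rois$roi_id)]), collapse = ", "),
         call. = FALSE)
  bad <- !rois$class %in% disease_classes()
  if (any(bad))
    stop("unknown disease class: ", paste(unique(rois$class[bad]),
                                          collapse = ", "), call. = FALSE)
  invisible(m)
}

#' Flatten a manifest into one row per ROI
#'
#' @param manifest a [cohort_manifest()].
#' @return a data.frame with columns `patient_id`, `slide_id`, `roi_id`,
#'   `class`, plus one column per covariate.
#' @export
manifest_rois <- function(manifest) {
  rows <- list()
  for (p in manifest$patients) {
    cov <- as.data.frame(lapply(p$covariates, identity),
                         stringsAsFactors = FALSE)
    for (s in p$slides) {
      for (r in s$rois) {
        row <- data.frame(patient_id = p$id, slide_id = s$id, roi_id = r,
                          class = p$class, stringsAsFactors = FALSE)
        if (ncol(cov) > 0) row <- cbind(row, cov)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(patient_id = character(), slide_id = character(),
                      roi_id = character(), class = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Per-patient summary of a manifest
#'
#' @param manifest a [cohort_manifest()].
#' @return a data.frame with one row per patient: `patient_id`, `class`,
#'   covariates, `n_slides`, `n_rois`.
#' @export
manifest_patients <- function(manifest) {
  rows <- lapply(manifest$patients, function(p) {
    cov <- as.data.frame(lapply(p$covariates, identity),
                         stringsAsFactors = FALSE)
    row <- data.frame(patient_id = p$id, class = p$class,
                      n_slides = length(p$slides),
                      n_rois = sum(vapply(p$slides,
                                          function(s) length(s$rois), 1L)),
                      stringsAsFactors = FALSE)
    if (ncol(cov) > 0) cbind(row, cov) else row
  })
  do.call(rbind, rows)
}

#' @export
print.cohort_manifest <- function(x, ...) {
  pts <- manifest_patients(x)
  cat(sprintf("<cohort_manifest> %d patients, %d slides, %d ROIs\n",
              nrow(pts), sum(pts$n_slides), sum(pts$n_rois)))
  print(table(pts$class))
  invisible(x)
}

#' Read and write cohort manifests as JSON
#'
#' @param manifest a [cohort_manifest()].
#' @param path file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns a [cohort_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(list(patients = manifest$patients), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  patients <- lapply(raw$patients, function(p) {
    p$slides <- lapply(p$slides, function(s) {
      s$rois <- as.character(unlist(s$rois))
      s
    })
    p
  })
  cohort_manifest(patients)
}
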