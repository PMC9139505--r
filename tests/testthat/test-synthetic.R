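test_that("generate_roi_cells is deterministic in the seed", {
  a <- generate_roi_cells("CLL", 300, seed = 42, contaminant_fraction = 0.05)
  b <- generate_roi_cells("CLL", 300, seed = 42, contaminant_fraction = 0.05)
  c <- generate_roi_cells("CLL", 300, seed = 43, contaminant_fraction = 0.05)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("generated cells satisfy the table invariants", {
  tab <- generate_roi_cells("aCLL", 1000, seed = 3,
                            contaminant_fraction = 0.1)
  expect_s3_class(tab, "cell_table")
  expect_equal(nrow(tab), 1000)
  expect_true(all(tab$mean_intensity >= 0 & tab$mean_intensity <= 255))
  expect_true(all(tab$solidity > 0 & tab$solidity <= 1))
  expect_true(all(tab$area_px >= 1))
  expect_true(all(tab$centroid_x_um >= 0 &
                    tab$centroid_x_um <= attr(tab, "roi_width_um")))
  expect_equal(tab$area_um2, tab$area_px * attr(tab, "resolution")^2)
  empty <- generate_roi_cells("RT", 0, seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("truth phenotype draws recover the configured mixture", {
  mix <- default_class_mixtures()$aCLL
  tab <- generate_roi_cells("aCLL", 20000, seed = 8)
  p_hat <- table(factor(tab$truth_phenotype,
                        levels = phenotype_names())) / nrow(tab)
  se <- sqrt(mix * (1 - mix) / nrow(tab))
  expect_true(all(abs(as.numeric(p_hat) - mix) <= 3 * se))
})

test_that("contaminants, and only (mostly) contaminants, violate QC", {
  tab <- generate_roi_cells("CLL", 2000, seed = 5,
                            contaminant_fraction = 0.5)
  violates <- tab$solidity < 0.84 | tab$area_px < 32 | tab$area_px > 432
  expect_true(all(violates[tab$contaminant]))
  expect_gt(mean(!violates[!tab$contaminant]), 0.95)
})

test_that("the QC filter retains about 1 - contaminant_fraction", {
  tab <- generate_roi_cells("RT", 5000, seed = 9,
                            contaminant_fraction = 0.2)
  kept <- nrow(filter_cells(tab)) / nrow(tab)
  expect_lt(abs(kept - 0.8), 0.03)
})

test_that("separated archetypes respect their size supports", {
  coh <- small_benchmark()
  gap <- attr(separated_phenotype_params(), "size_gap")
  expect_identical(gap, c(22, 28))
  cells <- do.call(rbind, lapply(coh$cells, as.data.frame))
  clean <- cells[!cells$contaminant, ]
  small <- clean$truth_phenotype != "RT-like"
  expect_true(all(clean$area_um2[small] <= gap[1] + 0.51))
  expect_true(all(clean$area_um2[!small] >= gap[2] - 0.51))
})

test_that("cohort hierarchy matches the manifest and config ranges", {
  cfg <- cohort_config(patients_per_class = 3, slides_per_patient = c(1, 2),
                       rois_per_slide = c(2, 4), cells_per_roi = c(50, 80),
                       seed = 12)
  coh <- generate_cohort(cfg)
  rois <- manifest_rois(coh$manifest)
  expect_setequal(names(coh$cells), rois$roi_id)
  pts <- manifest_patients(coh$manifest)
  expect_equal(as.vector(table(pts$class)[disease_classes()]), rep(3, 3))
  expect_true(all(pts$n_slides >= 1 & pts$n_slides <= 2))
  n_cells <- vapply(coh$cells, nrow, 1L)
  expect_true(all(n_cells >= 50 & n_cells <= 80))
  expect_true(all(c("gender_male", "age_ge60", "source_inhouse",
                    "biopsy_cnb", "os_shorter") %in% names(pts)))
})

test_that("any single ROI can be regenerated in isolation", {
  coh <- small_benchmark()
  rois <- small_rois()
  pick <- rois[5, ]
  cfg <- coh$config
  redo <- generate_roi_cells(
    pick$class, n_cells = nrow(coh$cells[[pick$roi_id]]),
    mixtures = coh$mixtures, params = coh$params,
    roi_width_px = cfg$roi_width_px, roi_height_px = cfg$roi_height_px,
    resolution = cfg$resolution,
    seed = derive_seed(cfg$seed, pick$patient_id, pick$slide_id,
                       pick$roi_id),
    contaminant_fraction = cfg$contaminant_fraction,
    roi_id = pick$roi_id, disease_label = pick$class)
  expect_identical(as.data.frame(redo),
                   as.data.frame(coh$cells[[pick$roi_id]]))
})

test_that("full cohorts are reproducible from the master seed", {
  cfg <- cohort_config(patients_per_class = 2, cells_per_roi = c(40, 60),
                       rois_per_slide = c(1, 2), seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(lapply(a$cells, as.data.frame),
                   lapply(b$cells, as.data.frame))
})

test_that("rendered masks reproduce the cells they encode", {
  tab <- generate_roi_cells("RT", 15, seed = 31, roi_width_px = 512,
                            roi_height_px = 512)
  r <- render_label_mask(tab, seed = 4)
  expect_gt(length(r$placed), 0)
  rec <- cells_from_mask(r$mask, r$image)
  expect_equal(nrow(rec), length(r$placed))
  expect_equal(rec$area_px, round(tab$area_px[r$placed]))
  expect_equal(rec$mean_intensity, round(tab$mean_intensity[r$placed]))
  expect_true(all(rec$solidity > 0.85))  # ellipses are convex
})

test_that("mask and image files round-trip exactly", {
  tab <- generate_roi_cells("CLL", 10, seed = 6, roi_width_px = 512,
                            roi_height_px = 512)
  r <- render_label_mask(tab, seed = 2)
  td <- withr::local_tempdir()
  write_label_mask(r$mask, file.path(td, "m.tif"))
  expect_identical(read_label_mask(file.path(td, "m.tif")), r$mask)
  write_grayscale_image(r$image, file.path(td, "g.png"))
  expect_identical(read_grayscale_image(file.path(td, "g.png")),
                   r$image)
  write_grayscale_image(r$image, file.path(td, "g.tif"))
  expect_identical(read_grayscale_image(file.path(td, "g.tif")),
                   r$image)
})

test_that("write_cohort writes a readable manifest and cell tables", {
  cfg <- cohort_config(patients_per_class = 2, rois_per_slide = c(1, 2),
                       cells_per_roi = c(30, 50), seed = 19)
  coh <- generate_cohort(cfg)
  td <- withr::local_tempdir()
  write_cohort(coh, td)
  m2 <- read_manifest(file.path(td, "manifest.json"))
  expect_identical(manifest_rois(m2), manifest_rois(coh$manifest))
  roi <- names(coh$cells)[1]
  back <- read_cell_table(file.path(td, "cells", paste0(roi, ".csv")))
  orig <- coh$cells[[roi]]
  expect_equal(back$area_px, orig$area_px)
  expect_equal(back$mean_intensity, orig$mean_intensity, tolerance = 1e-12)
  expect_equal(back$solidity, orig$solidity, tolerance = 1e-12)
  expect_equal(back$centroid_x_um, orig$centroid_x_um, tolerance = 1e-12)
  expect_identical(back$truth_phenotype, orig$truth_phenotype)
  expect_identical(attr(back, "disease_label"), attr(orig, "disease_label"))
  expect_identical(attr(back, "roi_width_um"), attr(orig, "roi_width_um"))
})
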