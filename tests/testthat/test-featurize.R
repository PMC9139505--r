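test_that("the feature families have the contracted sizes and order", {
  expect_length(feature_names("all"), 20)
  expect_length(feature_names("unsupervised"), 6)
  expect_length(feature_names("mixed"), 4)
  expect_length(feature_names("supervised"), 10)
  expect_identical(feature_names("all"),
                   c(feature_names("unsupervised"), feature_names("mixed"),
                     feature_names("supervised")))
  expect_false(anyDuplicated(feature_names("all")) > 0)
})

test_that("unsupervised features match hand-computed ratios/densities", {
  # ROI 1000 x 1000 px at 0.5 um/px = 500 x 500 um = 0.25 mm^2
  tab <- make_table(area_um2 = c(10, 11, 12, 40),
                    phenotype = c("CLL-like", "CLL-like", "CLL-like",
                                  "aCLL-like"))
  f <- unsupervised_features(tab)
  expect_equal(unname(f[c("cll_like_ratio", "acll_like_ratio",
                          "rt_like_ratio")]), c(0.75, 0.25, 0))
  expect_equal(unname(f[c("cll_like_density", "acll_like_density",
                          "rt_like_density")]), c(3, 1, 0) / 0.25)
  expect_error(unsupervised_features(make_table(10)), "no phenotype")
  expect_true(all(is.na(unsupervised_features(
    make_table(numeric(0), phenotype = character(0))))))
})

test_that("ratio and density partition identities hold", {
  for (tab in small_labeled()[1:5]) {
    f <- unsupervised_features(tab)
    m <- mixed_features(tab)
    expect_equal(sum(f[1:3]), 1)
    expect_equal(sum(f[4:6]), unname(m["cell_density"]))
  }
})

test_that("mixed features match hand arithmetic", {
  # collinear points at x = 0, 1, 3: NN distances 1, 1, 2
  tab <- make_table(area_um2 = c(10, 20, 30), intensity = c(90, 100, 110),
                    x = c(0, 1, 3), y = c(0, 0, 0))
  m <- mixed_features(tab)
  expect_equal(unname(m["mean_cell_size"]), 20)
  expect_equal(unname(m["mean_cell_intensity"]), 100)
  expect_equal(unname(m["mean_nn_dist"]), 4 / 3)
  expect_equal(unname(m["cell_density"]), 3 / 0.25)
  single <- make_table(10)
  expect_true(is.na(mixed_features(single)["mean_nn_dist"]))
  expect_equal(unname(mixed_features(single)["cell_density"]), 1 / 0.25)
})

test_that("mean_nn_distance handles cross-set and degenerate cases", {
  expect_equal(mean_nn_distance(cbind(0, 0), cbind(3, 4)), 5)
  expect_equal(mean_nn_distance(rbind(c(0, 0), c(10, 0)),
                                rbind(c(3, 4), c(10, 1))), 3)
  expect_true(is.na(mean_nn_distance(cbind(0, 0), cbind(0, 0)[0, , drop = FALSE])))
  expect_true(is.na(mean_nn_distance(cbind(0, 0), cbind(0, 0), same_set = TRUE)))
})

test_that("intensity PDF similarity matches its definitions", {
  same <- intensity_pdf_similarity(c(10, 50, 90), c(10, 50, 90))
  expect_equal(unname(same), c(1, 0, 0))
  # fully disjoint bin occupations: symmetric chi-square = 2
  disjoint <- intensity_pdf_similarity(rep(10, 5), rep(200, 5))
  expect_equal(unname(disjoint["sl_intensity_chisq"]), 2)
  expect_equal(unname(disjoint["sl_intensity_wasserstein"]), 190)
  shift <- intensity_pdf_similarity(c(10, 20, 30), c(10, 20, 30) + 8)
  expect_equal(unname(shift["sl_intensity_wasserstein"]), 8)
  expect_true(all(is.na(intensity_pdf_similarity(numeric(0), c(1, 2)))))
})

test_that("supervised features match hand arithmetic at a fixed cutoff", {
  # small: (0,0), (6,8); large: (3,4) -> s2l distances 5, 5; l2s 5
  tab <- make_table(area_um2 = c(10, 12, 40), intensity = c(100, 120, 200),
                    x = c(0, 6, 3), y = c(0, 8, 4))
  f <- supervised_features(tab, 24)
  expect_equal(unname(f["large_cell_ratio"]), 1 / 3)
  expect_equal(unname(f["small_cell_density"]), 2 / 0.25)
  expect_equal(unname(f["large_cell_density"]), 1 / 0.25)
  expect_equal(unname(f["s2s_nn_dist"]), 10)
  expect_equal(unname(f["s2l_nn_dist"]), 5)
  expect_equal(unname(f["l2s_nn_dist"]), 5)
  expect_true(is.na(f["l2l_nn_dist"]))  # one large cell: undefined, not 0
  expect_equal(unname(f["sl_intensity_wasserstein"]),
               wasserstein1d(c(100, 120), 200))
})

test_that("group preconditions give missing values, never zeros", {
  all_small <- make_table(area_um2 = c(10, 12, 14))
  f <- supervised_features(all_small, 24)
  expect_equal(unname(f["large_cell_ratio"]), 0)
  expect_true(all(is.na(f[c("sl_intensity_corr", "sl_intensity_chisq",
                            "sl_intensity_wasserstein", "s2l_nn_dist",
                            "l2s_nn_dist", "l2l_nn_dist")])))
  expect_equal(unname(f["large_cell_density"]), 0)
})

test_that("small and large densities partition the overall density", {
  for (tab in small_labeled()[1:5]) {
    f <- supervised_features(tab, 24)
    m <- mixed_features(tab)
    expect_equal(unname(f["small_cell_density"] + f["large_cell_density"]),
                 unname(m["cell_density"]))
  }
})

test_that("features are invariant to rigid translation of the ROI", {
  tab <- small_labeled()[[1]]
  moved <- as.data.frame(tab)
  moved$centroid_x_um <- moved$centroid_x_um -
    min(moved$centroid_x_um) + 1
  moved$centroid_y_um <- moved$centroid_y_um -
    min(moved$centroid_y_um) + 1
  moved <- cellpheno:::rewrap_cell_table(moved, tab)
  a <- featurize_roi(tab, 24)
  b <- featurize_roi(moved, 24)
  expect_equal(a[, feature_names("all")], b[, feature_names("all")])
})

test_that("featurize_roi yields the 20 named features per ROI", {
  row <- featurize_roi(small_labeled()[[1]], 24)
  expect_identical(names(row), c("roi_id", "label", feature_names("all")))
  expect_equal(nrow(row), 1)
  empty <- propagate_labels(small_model(),
                            filter_cells(generate_roi_cells("CLL", 0)))
  expect_true(all(is.na(featurize_roi(empty, 24)[, feature_names("all")])))
})

test_that("optimize_size_cutoff matches a brute-force oracle", {
  brute <- function(tables, grid) {
    labels <- vapply(tables, function(tb) attr(tb, "disease_label"), "")
    obj <- vapply(grid, function(cth) {
      r <- vapply(disease_classes(), function(cls) {
        mean(vapply(tables[labels == cls],
                    function(tb) mean(tb$area_um2 > cth), 1))
      }, 1)
      (r["RT"] - r["aCLL"]) * (r["aCLL"] - r["CLL"]) * (r["RT"] - r["CLL"])
    }, 1)
    list(cutoff = grid[which.max(obj)], objective = obj)
  }
  set.seed(55)
  for (i in 1:5) {
    tables <- unlist(lapply(disease_classes(), function(cls) {
      lapply(1:2, function(j)
        generate_roi_cells(cls, 80, seed = sample.int(1e6, 1),
                           roi_id = paste(cls, i, j)))
    }), recursive = FALSE)
    got <- optimize_size_cutoff(tables)
    want <- brute(tables, seq(8, 108, 1))
    expect_equal(got$optimal_cutoff_um2, want$cutoff)
    expect_equal(got$curve$objective, unname(want$objective))
  }
})

test_that("a flat objective ties to the smallest grid cutoff", {
  tables <- lapply(disease_classes(), function(cls)
    make_table(rep(15, 10), roi_id = paste0(cls, "-flat"), label = cls))
  cs <- optimize_size_cutoff(tables)
  expect_equal(cs$optimal_cutoff_um2, 8)
  expect_true(all(cs$curve$objective == 0))
})

test_that("cutoff search requires every class", {
  tables <- list(make_table(10, label = "CLL"),
                 make_table(12, label = "aCLL"))
  expect_error(optimize_size_cutoff(tables), "no training ROIs for class RT")
})

test_that("featurize_cohort attaches manifest patients and labels", {
  feats <- small_features()
  rois <- small_rois()
  expect_identical(names(feats),
                   c("roi_id", "patient_id", "label", feature_names("all")))
  expect_equal(nrow(feats), nrow(rois))
  m <- match(feats$roi_id, rois$roi_id)
  expect_identical(feats$patient_id, rois$patient_id[m])
  expect_identical(feats$label, rois$class[m])
})

test_that("feature CSVs round-trip including missing values", {
  feats <- small_features()
  feats$l2l_nn_dist[1] <- NA
  td <- withr::local_tempdir()
  write_features(feats, file.path(td, "f.csv"))
  back <- read_features(file.path(td, "f.csv"))
  expect_identical(names(back), names(feats))
  expect_true(is.na(back$l2l_nn_dist[1]))
  expect_equal(back$mean_cell_size, feats$mean_cell_size,
               tolerance = 1e-12)
})
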