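# ROI placement, trimmed-median representative HU, vBMD measurement.

test_that("window normalisation maps the window affinely onto [0, 1]", {
  expect_equal(window_normalize(300), 0.5)
  expect_equal(window_normalize(c(-125, 725)), c(0, 1))
  expect_equal(window_normalize(87.5), 0.25)
  expect_equal(window_normalize(c(-3000, 5000)), c(0, 1))  # clipping
  hu <- seq(-500, 1000, by = 7)
  expect_true(all(diff(window_normalize(hu)) >= 0))  # monotone
  sv <- fixture_spine2()
  wv <- window_normalize(sv$volume)
  expect_s3_class(wv, "ct_volume")
  expect_true(all(wv$voxels >= 0 & wv$voxels <= 1))
  expect_error(window_normalize(100, width = 0), class = "qct_bad_argument")
})

test_that("the ROI avoids cortical shell and vein channel", {
  sv <- fixture_spine2(c(100, 50))
  gt <- sv$ground_truth
  inst <- instance_label(segment_lumbar(sv$volume, gt, method = "oracle"))
  dims <- dim(sv$volume$voxels)
  for (lv in c("L1", "L2")) {
    roi <- place_roi(inst[[lv]])
    expect_gte(roi$n_voxels, 50)
    lin <- roi_linear_index(roi, dims)
    expect_equal(sum(gt$tissue[lin] == TISSUE["cortical"]), 0)
    expect_equal(sum(gt$tissue[lin] == TISSUE["vein"]), 0)
    # ROI voxels all belong to the instance's own body
    expect_true(all(gt$instance_mask[lin] == which(c("L1", "L2") == lv)))
  }
})

test_that("erosion larger than the body is an infeasible-ROI error", {
  sv <- cached("spine_tiny", generate_vertebra_volume(
    vertebra_spec("L1", 100, body_radius_mm = c(2.5, 2.5),
                  cortical_thickness_mm = 1, vein_channel = FALSE),
    dims_xy = c(48, 48)))
  inst <- instance_label(segment_lumbar(sv$volume, sv$ground_truth,
                                        method = "oracle"), min_voxels = 10)
  expect_error(place_roi(inst$L1, roi_config(erosion_mm = 3)),
               class = "qct_roi_infeasible")
})

test_that("representative HU equals the naive sort-trim-median oracle", {
  # constant distribution
  r <- representative_hu(NULL, rep(100, 100))
  expect_equal(r$value, 100)
  expect_equal(r$n_raw, 100)
  expect_equal(r$n_used, 100)  # floor(0.005 * 100) = 0 per tail
  # uniform 0..999, 1% symmetric trim: 5 per tail, median of 5..994
  r2 <- representative_hu(NULL, sample(0:999), trim_fraction = 0.01)
  expect_equal(r2$value, 499.5)
  expect_equal(r2$n_used, 990)
  # seeded Gaussian with gross high outliers
  withr::with_seed(11, {
    x <- c(rnorm(500, 100, 10), rep(800, 5))
  })
  r3 <- representative_hu(NULL, x, trim_fraction = 0.01)
  expect_true(r3$value >= 97 && r3$value <= 103)
  expect_equal(r3$value, oracle_trimmed_median(x, 0.01))
  expect_error(representative_hu(NULL, numeric(0)), class = "qct_empty_roi")
  expect_error(representative_hu(NULL, 1:10, trim_fraction = 0.6),
               class = "qct_bad_argument")
})

test_that("a small admixture of extreme voxels barely moves the trimmed median", {
  withr::with_seed(12, x <- rnorm(2000, 100, 10))
  base <- representative_hu(NULL, x)$value
  contaminated <- c(x, rep(2000, floor(0.005 * length(x))))
  expect_lt(abs(representative_hu(NULL, contaminated)$value - base), 1)
})

test_that("vBMD measurement recovers painted densities and averages L1/L2", {
  sv <- fixture_spine2(c(100, 100))
  inst <- instance_label(segment_lumbar(sv$volume, sv$ground_truth,
                                        method = "oracle"))
  res <- measure_vbmd(sv$volume, inst, identity_model())
  expect_equal(res$combined_L1_2, 100)
  expect_false(res$single_vertebra)

  sv2 <- fixture_spine2(c(90, 110))
  inst2 <- instance_label(segment_lumbar(sv2$volume, sv2$ground_truth,
                                         method = "oracle"))
  res2 <- measure_vbmd(sv2$volume, inst2, identity_model())
  expect_equal(unname(res2$per_vertebra["L1"]), 90)
  expect_equal(unname(res2$per_vertebra["L2"]), 110)
  expect_equal(res2$combined_L1_2, 100)
})

test_that("an L1-only scan yields a flagged single-vertebra measurement", {
  sv <- cached("spine1_95", generate_vertebra_volume(
    vertebra_spec("L1", 95), noise_sigma = 0))
  inst <- instance_label(segment_lumbar(sv$volume, sv$ground_truth,
                                        method = "oracle"))
  res <- measure_vbmd(sv$volume, inst, identity_model())
  expect_true(res$single_vertebra)
  expect_equal(res$combined_L1_2, unname(res$per_vertebra["L1"]))
})

test_that("a protocol mismatch between model and volume is an error", {
  sv <- fixture_spine2()
  inst <- instance_label(segment_lumbar(sv$volume, sv$ground_truth,
                                        method = "oracle"))
  expect_error(
    measure_vbmd(sv$volume, inst, identity_model(protocol = "other/100kVp")),
    class = "qct_protocol_mismatch")
})

test_that("end-to-end density recovery is accurate under noise", {
  for (dens in c(60, 160)) {
    sv <- generate_vertebra_volume(
      list(vertebra_spec("L1", dens), vertebra_spec("L2", dens)),
      noise_sigma = 10, seed = 100 + dens)
    inst <- instance_label(segment_lumbar(sv$volume))
    res <- measure_vbmd(sv$volume, inst, identity_model())
    expect_gte(min(vapply(res$rois, `[[`, numeric(1), "n_voxels")), 500)
    expect_lt(abs(res$combined_L1_2 - dens), 5)
  }
})
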