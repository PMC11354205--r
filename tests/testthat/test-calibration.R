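# Phantom calibration: sampling, six regressions, selection, conversion.

test_that("noise-free insert sampling yields exact per-slice HU rows", {
  s <- extract_insert_hu(fixture_phantom(sigma = 0, n_slices = 20))
  expect_equal(nrow(s), 60)
  expect_equal(sort(unique(s$density)), c(50, 100, 200))
  for (d in c(50, 100, 200)) expect_true(all(s$hu[s$density == d] == d))
})

test_that("inserts covered by too few slices are rejected", {
  ph <- fixture_phantom(sigma = 0, n_slices = 20)
  thin <- list(volume = ct_volume(ph$volume$voxels[, , 1, drop = FALSE],
                                  protocol = ph$protocol),
               insert_masks = ph$insert_masks[, , 1, drop = FALSE],
               insert_densities = ph$insert_densities,
               protocol = ph$protocol)
  expect_error(extract_insert_hu(thin), class = "qct_insufficient_samples")
})

test_that("noisy insert HU means stay near the painted densities", {
  s <- extract_insert_hu(fixture_phantom(sigma = 5, n_slices = 20, seed = 9))
  means <- tapply(s$hu, s$density, mean)
  expect_true(all(abs(means - c(50, 100, 200)) < 2.5))
})

test_that("the linear candidate recovers affine ground truth exactly", {
  cand <- fit_conversion(extract_insert_hu(fixture_phantom(sigma = 0)))
  lin <- cand[[which(vapply(cand, `[[`, character(1), "method") == "linear")]]
  expect_equal(lin$coefficients$slope, 1, tolerance = 1e-9)
  expect_equal(lin$coefficients$intercept, 0, tolerance = 1e-7)
  expect_lt(lin$rmse, 1e-7)
  # HU = 2*BMD + 10  =>  BMD = 0.5*HU - 5
  cand2 <- fit_conversion(extract_insert_hu(
    fixture_phantom(sigma = 0, slope = 2, intercept = 10)))
  lin2 <- cand2[[which(vapply(cand2, `[[`, character(1), "method") == "linear")]]
  expect_equal(lin2$coefficients$slope, 0.5, tolerance = 1e-9)
  expect_equal(lin2$coefficients$intercept, -5, tolerance = 1e-7)
  # noise-free selected model reproduces all three inserts
  sel <- select_model(cand)
  expect_equal(convert_hu_to_bmd(sel, c(50, 100, 200)), c(50, 100, 200),
               tolerance = 1e-6)
})

test_that("candidates come back sorted by RMSE with the best first", {
  cand <- fit_conversion(extract_insert_hu(
    fixture_phantom(sigma = 5, n_slices = 20, seed = 9)))
  rmse <- vapply(cand, `[[`, numeric(1), "rmse")
  expect_true(!is.unsorted(rmse))
  sel <- select_model(cand)
  expect_false(needs_recalibration(sel))
  expect_lt(sel$rmse, 5)
  expect_true(all(sel$rmse <= rmse))
})

test_that("selection applies the strict recalibration rule", {
  mk <- function(rmse) qctscreen:::new_conversion_model(
    "linear", list(intercept = 0, slope = 1), rmse, "p", c(0, 300), TRUE, 60)
  expect_equal(select_model(list(mk(0.4), mk(2.2), mk(7)))$rmse, 0.4)
  sig <- select_model(list(mk(6.1), mk(7), mk(12)))
  expect_true(needs_recalibration(sig))
  expect_equal(sig$best_rmse, 6.1)
  # RMSE exactly at the threshold is accepted ("exceeded" is strict)
  expect_false(needs_recalibration(select_model(list(mk(5.0)))))
})

test_that("a degenerate design fails per method, not fatally, until all fail", {
  s <- data.frame(density = rep(c(50, 100, 200), each = 3),
                  slice = rep(1:3, 3), hu = 100)
  expect_error(fit_conversion(s), class = "qct_calibration_failure")
})

test_that("conversion evaluates the fitted equation and respects its domain", {
  expect_equal(convert_hu_to_bmd(identity_model(), 123.4), 123.4)
  m <- qctscreen:::new_conversion_model(
    "linear", list(intercept = -5, slope = 0.5), 0, "p", c(-100, 500), TRUE, 60)
  expect_equal(convert_hu_to_bmd(m, 210), 100)
  expect_equal(convert_hu_to_bmd(m, c(10, 210)), c(0, 100))
  expect_error(convert_hu_to_bmd(m, 1000, clamp = FALSE),
               class = "qct_domain_error")
  expect_equal(convert_hu_to_bmd(m, 1000), convert_hu_to_bmd(m, 500))
  # identity calibration maps the osteoporosis boundary onto itself
  sel <- select_model(fit_conversion(extract_insert_hu(fixture_phantom())))
  expect_equal(convert_hu_to_bmd(sel, 80), 80, tolerance = 1e-6)
})

test_that("calibration-then-conversion recovers painted insert densities under noise", {
  sigma <- 5; n_slices <- 20
  ph <- fixture_phantom(sigma = sigma, n_slices = n_slices, seed = 17)
  s <- extract_insert_hu(ph)
  sel <- select_model(fit_conversion(s))
  for (d in c(50, 100, 200)) {
    est <- convert_hu_to_bmd(sel, mean(s$hu[s$density == d]))
    expect_lt(abs(est - d), 2 * sigma / sqrt(n_slices))
  }
})

test_that("conversion models survive a JSON round trip", {
  sel <- select_model(fit_conversion(extract_insert_hu(
    fixture_phantom(sigma = 5, n_slices = 20, seed = 9))))
  path <- withr::local_tempfile(fileext = ".json")
  write_conversion_model(sel, path)
  back <- read_conversion_model(path)
  expect_equal(back$method, sel$method)
  expect_equal(back$coefficients, sel$coefficients)
  expect_equal(back$rmse, sel$rmse)
  expect_equal(back$protocol, sel$protocol)
  hu <- seq(10, 250, by = 10)
  expect_equal(convert_hu_to_bmd(back, hu), convert_hu_to_bmd(sel, hu))
})
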