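# Shared fixtures, generated in code and cached per test run.

`%||%` <- function(x, y) if (is.null(x)) y else x

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# a two-vertebra lumbar volume painted with the identity HU model
fixture_spine2 <- function(densities = c(100, 50), sigma = 0, seed = 1) {
  key <- paste0("spine2_", paste(densities, collapse = "_"), "_", sigma,
                "_", seed)
  cached(key, generate_vertebra_volume(
    list(vertebra_spec("L1", densities[1]), vertebra_spec("L2", densities[2])),
    noise_sigma = sigma, seed = seed))
}

fixture_phantom <- function(sigma = 0, n_slices = 20, seed = 1, slope = 1,
                            intercept = 0) {
  key <- paste0("ph_", sigma, "_", n_slices, "_", seed, "_", slope, "_",
                intercept)
  cached(key, generate_esp_volume(hu_slope = slope, hu_intercept = intercept,
                                  noise_sigma = sigma, n_slices = n_slices,
                                  seed = seed))
}

# classified synthetic cohort (true vBMD used directly as the measurement)
fixture_classified_cohort <- function(n = 1500, seed = 5) {
  cached(paste0("cohort_", n, "_", seed), {
    rec <- sample_cohort(n, seed = seed)
    rec$vbmd <- rec$true_vbmd
    rec$category <- classify_acr(rec$vbmd)
    rec
  })
}

# linear voxel offsets of an ROI, for intersection tests against masks
roi_linear_index <- function(roi, dims) {
  v <- roi$voxel_indices
  v[, 1] + (v[, 2] - 1L) * dims[1] + (v[, 3] - 1L) * dims[1] * dims[2]
}

# independent sort-trim-median oracle (naive restatement of the rule)
oracle_trimmed_median <- function(x, trim) {
  n <- length(x)
  k <- floor(trim / 2 * n)
  s <- sort(x)
  stats::median(if (k > 0) s[(k + 1):(n - k)] else s)
}
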