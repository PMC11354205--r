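# End-to-end orchestration: simulate -> calibrate -> segment -> measure ->
# classify -> report, with an echoed config and a flowchart-style log.

#' Pipeline configuration
#'
#' Collects every stage parameter and output path of the end-to-end run in
#' one serializable object; the configuration is echoed as JSON next to the
#' outputs so a run is reproducible from its own records. All randomness
#' derives from the single `seed`.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; per-participant imaging seeds are derived from
#'   it.
#' @param n_participants cohort size to simulate.
#' @param exclusion_counts `(missing_L1, fracture_implant)` counts.
#' @param noise_sigma HU noise of the simulated patient scans.
#' @param phantom_sigma,phantom_slices phantom noise and slice count.
#' @param hu_slope,hu_intercept ground-truth HU model of the simulator.
#' @param segmentation `"rule_based"` or `"oracle"`.
#' @param erosion_mm,trim_fraction,rmse_threshold,min_age stage parameters
#'   (see [roi_config()], [select_model()], [crude_prevalence()]).
#' @param dims_xy in-plane dimensions of the simulated patient volumes.
#' @param body_radius_mm in-plane semi-axes of the simulated vertebrae.
#' @param standard_population path to a standard-population CSV; defaults to
#'   the bundled synthetic standard.
#' @param protocol protocol key shared by phantom and patient volumes.
#' @param verbose print per-stage progress.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_participants = 30L,
                            exclusion_counts = c(missing_L1 = 2L,
                                                 fracture_implant = 1L),
                            noise_sigma = 10, phantom_sigma = 5,
                            phantom_slices = 20L, hu_slope = 1,
                            hu_intercept = 0,
                            segmentation = c("rule_based", "oracle"),
                            erosion_mm = 3, trim_fraction = 0.01,
                            rmse_threshold = 5.0, min_age = 50,
                            dims_xy = c(96, 96), body_radius_mm = c(15, 12),
                            standard_population = NULL, protocol =
                              "sim/120kVp/standard", verbose = FALSE) {
  segmentation <- match.arg(segmentation)
  standard_population <- standard_population %||% system.file(
    "extdata", "standard_population_synthetic.csv", package = "qctscreen")
  if (!file.exists(standard_population))
    qct_abort(paste("standard population file not found:",
                    standard_population), "qct_bad_argument")
  if (trim_fraction < 0 || trim_fraction >= 0.5 || erosion_mm <= 0 ||
      rmse_threshold < 0)
    qct_abort("pipeline parameter out of range", "qct_bad_argument")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 exclusion_counts = exclusion_counts,
                 noise_sigma = noise_sigma, phantom_sigma = phantom_sigma,
                 phantom_slices = as.integer(phantom_slices),
                 hu_slope = hu_slope, hu_intercept = hu_intercept,
                 segmentation = segmentation, erosion_mm = erosion_mm,
                 trim_fraction = trim_fraction,
                 rmse_threshold = rmse_threshold, min_age = min_age,
                 dims_xy = dims_xy, body_radius_mm = body_radius_mm,
                 standard_population = standard_population,
                 protocol = protocol, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Stages: (1) simulate an ESP-like phantom and calibrate the HU-to-BMD
#' conversion (six candidate regressions, RMSE selection; an over-threshold
#' best RMSE stops the run with status `"recalibration_needed"`);
#' (2) simulate a cohort and apply the exclusion flowchart; (3) for every
#' included participant, simulate an L1+L2 scan at their true density,
#' segment it, place trabecular ROIs and measure vBMD; (4) classify by the
#' ACR criteria and build stratified and prevalence tables. Outputs
#' (cohort, measurement and report CSVs, model JSON, echoed config, log)
#' are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list: `status` (`"ok"` or
#'   `"recalibration_needed"`), `model`, `cohort`, `tally`, `measurements`,
#'   `report`, `stratified`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    config = file.path(config$out_dir, "config.json"),
    log = file.path(config$out_dir, "pipeline.log"),
    cohort = file.path(config$out_dir, "cohort.csv"),
    model = file.path(config$out_dir, "model.json"),
    samples = file.path(config$out_dir, "calibration_samples.csv"),
    measurements = file.path(config$out_dir, "measurements.csv"),
    stratified = file.path(config$out_dir, "stratified_bmd.csv"),
    report = file.path(config$out_dir, "prevalence.csv"),
    summary = file.path(config$out_dir, "summary.txt"))
  cfg_doc <- unclass(config)
  jsonlite::write_json(cfg_doc, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    log_lines <<- c(log_lines, line)
    if (config$verbose) message(line)
  }
  finish <- function(res) {
    writeLines(log_lines, paths$log)
    res
  }

  say("stage calibrate: simulating phantom (", config$phantom_slices,
      " slices, sigma ", config$phantom_sigma, ")")
  phantom <- generate_esp_volume(
    hu_slope = config$hu_slope, hu_intercept = config$hu_intercept,
    noise_sigma = config$phantom_sigma, n_slices = config$phantom_slices,
    seed = config$seed, protocol = config$protocol)
  samples <- extract_insert_hu(phantom, config$trim_fraction)
  utils::write.csv(as.data.frame(samples), paths$samples, row.names = FALSE)
  model <- select_model(fit_conversion(samples),
                        config$rmse_threshold)
  if (needs_recalibration(model)) {
    say("stage calibrate: best RMSE ", signif(model$best_rmse, 4),
        " mg/cc exceeds threshold ", config$rmse_threshold,
        " -> recalibration needed")
    return(finish(structure(list(status = "recalibration_needed",
                                 model = model, paths = paths),
                            class = "pipeline_result")))
  }
  say("stage calibrate: selected ", model$method, " (RMSE ",
      signif(model$rmse, 4), " mg/cc)")
  write_conversion_model(model, paths$model)

  say("stage simulate: cohort of ", config$n_participants)
  cohort <- sample_cohort(config$n_participants,
                          exclusion_counts = config$exclusion_counts,
                          seed = config$seed)
  write_cohort(cohort, paths$cohort)
  excl <- apply_exclusions(cohort)
  say("stage exclude: input ", excl$tally[["input"]], ", excluded ",
      excl$tally[["missing_L1"]], " (missing L1) + ",
      excl$tally[["fracture_implant"]], " (fracture/implant), included ",
      excl$tally[["included"]])

  inc <- excl$included
  rows <- list()
  for (i in seq_len(nrow(inc))) {
    pseed <- (config$seed * 10007L + i) %% .Machine$integer.max
    truth <- inc$true_vbmd[i]
    sv <- generate_vertebra_volume(
      list(vertebra_spec("L1", truth, body_radius_mm = config$body_radius_mm),
           vertebra_spec("L2", truth, body_radius_mm = config$body_radius_mm)),
      hu_slope = config$hu_slope, hu_intercept = config$hu_intercept,
      noise_sigma = config$noise_sigma, seed = pseed,
      dims_xy = config$dims_xy, protocol = config$protocol)
    res <- tryCatch({
      mask <- segment_lumbar(sv$volume, sv$ground_truth,
                             method = config$segmentation)
      instances <- instance_label(mask)
      measure_vbmd(sv$volume, instances, model,
                   roi_config(erosion_mm = config$erosion_mm,
                              trim_fraction = config$trim_fraction))
    }, qct_error = function(e) e)
    if (inherits(res, "error")) {
      say("stage measure: ", inc$id[i], " failed: ", conditionMessage(res))
      rows[[i]] <- data.frame(id = inc$id[i], age = inc$age[i],
                              sex = inc$sex[i], true_vbmd = truth,
                              vbmd = NA_real_, n_vertebrae = 0L,
                              single_vertebra = NA,
                              measurement_failed = TRUE,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(id = inc$id[i], age = inc$age[i],
                              sex = inc$sex[i], true_vbmd = truth,
                              vbmd = res$combined_L1_2,
                              n_vertebrae = length(res$per_vertebra),
                              single_vertebra = res$single_vertebra,
                              measurement_failed = FALSE,
                              stringsAsFactors = FALSE)
    }
  }
  meas <- do.call(rbind, rows)
  say("stage measure: ", sum(!meas$measurement_failed), "/", nrow(meas),
      " participants measured")
  utils::write.csv(meas, paths$measurements, row.names = FALSE)

  ok <- meas[!meas$measurement_failed, , drop = FALSE]
  ok$category <- classify_acr(ok$vbmd)
  say("stage classify: ", paste(names(table(ok$category)),
                                as.integer(table(ok$category)),
                                sep = "=", collapse = ", "))
  strat <- stratify_bmd(ok)
  utils::write.csv(strat, paths$stratified, row.names = FALSE)
  standard <- read_standard_population(config$standard_population)
  report <- prevalence_report(ok, standard, config$min_age)
  write_prevalence_report(report, paths$report, paths$summary)
  say("stage report: written to ", paths$report)

  finish(structure(list(status = "ok", model = model, cohort = cohort,
                        tally = excl$tally, measurements = meas,
                        classified = ok, stratified = strat,
                        report = report, paths = paths),
                   class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> status:", x$status, "\n")
  if (x$status == "ok") {
    cat("  measured:", sum(!x$measurements$measurement_failed), "of",
        nrow(x$measurements), "included participants\n")
    cat("  outputs under:", dirname(x$paths$config), "\n")
  }
  invisible(x)
}
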