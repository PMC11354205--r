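# Phantom-based HU -> BMD calibration: per-insert per-slice trimmed-median
# samples, six candidate regression families, RMSE-based selection with a
# recalibration rule, and application of the selected equation.

#' Extract per-insert per-slice HU samples from a phantom scan
#'
#' For every insert and every axial slice it intersects, computes the same
#' trimmed-median representative HU used for patient vertebrae, yielding one
#' calibration row per (insert, slice).
#'
#' @param phantom a `phantom_scan` from [generate_esp_volume()] (or an
#'   equivalent list with `volume`, `insert_masks`, `insert_densities`).
#' @param trim_fraction trimmed fraction passed to the median operator.
#' @return a `calibration_samples` data frame with columns `density`
#'   (mg/cc), `slice`, `hu`; the protocol key is kept in
#'   `attr(, "protocol")`.
#' @export
extract_insert_hu <- function(phantom, trim_fraction = 0.01) {
  vol <- phantom$volume
  masks <- phantom$insert_masks
  dens <- phantom$insert_densities
  si <- superior_axis(vol)$axis
  nz <- dim(vol$voxels)[si]
  rows <- list()
  for (k in seq_along(dens)) {
    zs <- which(vapply(seq_len(nz), function(z) {
      sl <- if (si == 3) masks[, , z] else if (si == 2) masks[, z, ]
            else masks[z, , ]
      any(sl == k)
    }, logical(1)))
    if (length(zs) < 3)
      qct_abort(sprintf(
        "insert %d (%g mg/cc) intersects only %d slice(s); need >= 3",
        k, dens[k], length(zs)), "qct_insufficient_samples")
    for (z in zs) {
      if (si == 3) {
        vals <- vol$voxels[, , z][masks[, , z] == k]
      } else if (si == 2) {
        vals <- vol$voxels[, z, ][masks[, z, ] == k]
      } else vals <- vol$voxels[z, , ][masks[z, , ] == k]
      rows[[length(rows) + 1L]] <- data.frame(
        density = dens[k], slice = z,
        hu = trim_median(vals, trim_fraction)$value)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "protocol") <- phantom$protocol %||% vol$protocol
  class(out) <- c("calibration_samples", "data.frame")
  out
}

new_conversion_model <- function(method, coefficients, rmse, protocol,
                                 hu_domain, monotone, n_samples) {
  structure(list(method = method, coefficients = coefficients, rmse = rmse,
                 protocol = protocol, hu_domain = hu_domain,
                 monotone = monotone, n_samples = n_samples),
            class = "conversion_model")
}

# evaluate a fitted equation on raw HU (no domain handling)
eval_model <- function(model, hu) {
  cf <- model$coefficients
  switch(model$method,
    linear = cf[["intercept"]] + cf[["slope"]] * hu,
    robust_linear = cf[["intercept"]] + cf[["slope"]] * hu,
    quadratic = cf[["b0"]] + cf[["b1"]] * hu + cf[["b2"]] * hu^2,
    power = cf[["a"]] * hu^cf[["b"]],
    logarithmic = cf[["a"]] + cf[["b"]] * log(hu),
    exponential = cf[["a"]] * exp(cf[["b"]] * hu),
    qct_abort(paste("unknown method", model$method), "qct_bad_argument"))
}

# Theil-Sen estimator: median of pairwise slopes, median-residual intercept
theil_sen <- function(hu, bmd) {
  n <- length(hu)
  pairs <- utils::combn(n, 2)
  dh <- hu[pairs[2, ]] - hu[pairs[1, ]]
  db <- bmd[pairs[2, ]] - bmd[pairs[1, ]]
  ok <- dh != 0
  if (!any(ok)) qct_abort("all HU values equal", "qct_fit_failure")
  slope <- stats::median(db[ok] / dh[ok])
  c(intercept = stats::median(bmd - slope * hu), slope = slope)
}

#' Fit the six candidate HU-to-BMD conversion equations
#'
#' Fits BMD as a function of HU by least squares for the linear, quadratic,
#' power (`a * HU^b`), logarithmic (`a + b log HU`) and exponential
#' (`a e^{b HU}`) families (the latter three in log space, requiring
#' positive values), plus a robust linear fit by the median of pairwise
#' slopes. Each candidate's RMSE is the root mean squared error of predicted
#' versus true insert density over all calibration rows, in mg/cc.
#' Candidates are returned sorted by RMSE ascending; on ties, monotone
#' candidates precede non-monotone ones and fewer parameters win.
#'
#' @param samples a `calibration_samples` data frame (`density`, `hu`).
#' @param protocol protocol key recorded in the models; defaults to the
#'   samples' attribute.
#' @return a `conversion_candidates` list of `conversion_model` objects,
#'   sorted by RMSE; per-method fit failures are recorded in
#'   `attr(, "failures")`. Raises a `qct_calibration_failure` if every
#'   method fails.
#' @export
fit_conversion <- function(samples, protocol = NULL) {
  protocol <- protocol %||% attr(samples, "protocol") %||% "unknown"
  hu <- samples$hu; bmd <- samples$density
  if (length(unique(bmd)) < 3)
    qct_abort("need at least 3 distinct densities", "qct_insufficient_samples")
  if (nrow(samples) <= 3)
    qct_abort("need more rows than the largest model's parameter count",
              "qct_insufficient_samples")
  hu_domain <- range(hu) + c(-50, 50)

  fit_one <- function(method) {
    cf <- switch(method,
      linear = {
        f <- stats::lm(bmd ~ hu)
        c(intercept = unname(stats::coef(f)[1]),
          slope = unname(stats::coef(f)[2]))
      },
      quadratic = {
        f <- stats::lm(bmd ~ hu + I(hu^2))
        c(b0 = unname(stats::coef(f)[1]), b1 = unname(stats::coef(f)[2]),
          b2 = unname(stats::coef(f)[3]))
      },
      power = {
        if (any(hu <= 0) || any(bmd <= 0))
          qct_abort("power fit needs positive HU and BMD", "qct_fit_failure")
        f <- stats::lm(log(bmd) ~ log(hu))
        c(a = exp(unname(stats::coef(f)[1])), b = unname(stats::coef(f)[2]))
      },
      logarithmic = {
        if (any(hu <= 0))
          qct_abort("logarithmic fit needs positive HU", "qct_fit_failure")
        f <- stats::lm(bmd ~ log(hu))
        c(a = unname(stats::coef(f)[1]), b = unname(stats::coef(f)[2]))
      },
      exponential = {
        if (any(bmd <= 0))
          qct_abort("exponential fit needs positive BMD", "qct_fit_failure")
        f <- stats::lm(log(bmd) ~ hu)
        c(a = exp(unname(stats::coef(f)[1])), b = unname(stats::coef(f)[2]))
      },
      robust_linear = theil_sen(hu, bmd))
    if (any(!is.finite(cf)))
      qct_abort("non-finite coefficients", "qct_fit_failure")
    dom <- hu_domain
    # log-family models are only defined for positive HU
    if (method %in% c("power", "logarithmic"))
      dom[1] <- max(dom[1], min(hu[hu > 0]) / 2)
    m <- new_conversion_model(method, as.list(cf), NA_real_, protocol,
                              dom, NA, nrow(samples))
    pred <- eval_model(m, hu)
    if (any(!is.finite(pred)))
      qct_abort("non-finite predictions", "qct_fit_failure")
    m$rmse <- sqrt(mean((pred - bmd)^2))
    grid <- seq(dom[1], dom[2], length.out = 200)
    m$monotone <- all(diff(eval_model(m, grid)) >= -1e-9)
    m
  }

  methods <- c("linear", "quadratic", "power", "logarithmic", "exponential",
               "robust_linear")
  fits <- list(); failures <- character(0)
  for (method in methods) {
    res <- tryCatch(fit_one(method), error = function(e) e)
    if (inherits(res, "error")) failures[method] <- conditionMessage(res)
    else fits[[method]] <- res
  }
  if (!length(fits))
    qct_abort(paste("every regression method failed:",
                    paste(failures, collapse = "; ")),
              "qct_calibration_failure")
  rmse <- vapply(fits, `[[`, numeric(1), "rmse")
  npar <- vapply(fits, function(m) length(m$coefficients), numeric(1))
  mono <- vapply(fits, `[[`, logical(1), "monotone")
  fits <- fits[order(rmse, !mono, npar)]
  structure(fits, class = "conversion_candidates", failures = failures)
}

#' Select the conversion model, or signal recalibration
#'
#' Returns the lowest-RMSE candidate provided its RMSE does not exceed
#' `rmse_threshold` (strict: a model at exactly the threshold is accepted).
#' Otherwise returns a `recalibration_signal` instructing re-acquisition of
#' phantom samples; an over-threshold model is never returned silently.
#'
#' @param candidates a `conversion_candidates` list from [fit_conversion()].
#' @param rmse_threshold recalibration bound in mg/cc (default 5.0).
#' @return a `conversion_model`, or a `recalibration_signal` (check with
#'   [needs_recalibration()]).
#' @export
select_model <- function(candidates, rmse_threshold = 5.0) {
  if (!length(candidates))
    qct_abort("no successfully fitted candidate", "qct_calibration_failure")
  best <- candidates[[1]]
  if (best$rmse > rmse_threshold)
    return(structure(list(best_method = best$method, best_rmse = best$rmse,
                          rmse_threshold = rmse_threshold),
                     class = "recalibration_signal"))
  best
}

#' @rdname select_model
#' @param x object to test.
#' @export
needs_recalibration <- function(x) inherits(x, "recalibration_signal")

#' Convert representative HU to vBMD
#'
#' Evaluates the fitted conversion equation. Inputs outside the model's HU
#' domain are clamped to it by default; with `clamp = FALSE` they raise a
#' domain error.
#'
#' @param model a `conversion_model`.
#' @param hu numeric vector of HU values.
#' @param clamp clamp out-of-domain inputs to `model$hu_domain`?
#' @return vBMD in mg/cm^3, same length as `hu`.
#' @export
convert_hu_to_bmd <- function(model, hu, clamp = TRUE) {
  dom <- model$hu_domain
  if (!is.null(dom)) {
    out_of <- hu < dom[1] | hu > dom[2]
    if (any(out_of)) {
      if (!clamp)
        qct_abort(sprintf("HU value outside model domain [%g, %g]",
                          dom[1], dom[2]), "qct_domain_error")
      hu <- pmin(pmax(hu, dom[1]), dom[2])
    }
  }
  out <- eval_model(model, hu)
  if (any(!is.finite(out)))
    qct_abort("conversion produced non-finite vBMD", "qct_domain_error")
  out
}

#' @export
print.conversion_model <- function(x, ...) {
  cat("<conversion_model> ", x$method, ": BMD(mg/cc) from HU, coefficients (",
      paste(sprintf("%s=%.6g", names(x$coefficients),
                    unlist(x$coefficients)), collapse = ", "),
      ")\n  RMSE ", signif(x$rmse, 4), " mg/cc, protocol ", x$protocol,
      ", HU domain [", round(x$hu_domain[1], 1), ", ",
      round(x$hu_domain[2], 1), "]\n", sep = "")
  invisible(x)
}

#' Serialize and restore conversion models as JSON
#'
#' The document records the method, coefficients, RMSE, protocol key, HU
#' domain, monotonicity flag and a format version, so a saved model is
#' self-describing.
#'
#' @param model a `conversion_model`.
#' @param path JSON file path.
#' @return `write_conversion_model()` returns `path` invisibly;
#'   `read_conversion_model()` the restored `conversion_model`.
#' @export
write_conversion_model <- function(model, path) {
  doc <- list(format = "qctscreen/conversion_model/1", method = model$method,
              coefficients = model$coefficients, rmse = model$rmse,
              protocol = model$protocol, hu_domain = model$hu_domain,
              monotone = model$monotone, n_samples = model$n_samples)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_conversion_model
#' @export
read_conversion_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_conversion_model(doc$method, as.list(doc$coefficients), doc$rmse,
                       doc$protocol, doc$hu_domain, doc$monotone,
                       doc$n_samples %||% NA_integer_)
}

#' Build an identity conversion model
#'
#' A convenience linear model `BMD = HU`, useful when volumes are painted
#' with the identity HU model (slope 1, intercept 0), e.g. in tests and
#' demos.
#'
#' @param protocol protocol key.
#' @param hu_domain valid HU input range.
#' @return a `conversion_model`.
#' @export
identity_model <- function(protocol = "sim/120kVp/standard",
                           hu_domain = c(-2000, 4000)) {
  new_conversion_model("linear", list(intercept = 0, slope = 1), 0,
                       protocol, hu_domain, TRUE, NA_integer_)
}
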