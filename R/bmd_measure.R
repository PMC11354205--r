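# Trabecular ROI placement, trimmed-median representative HU, and vBMD
# measurement for L1/L2.

#' Window-level/width intensity normalisation
#'
#' Clips HU to `[level - width/2, level + width/2]` and maps the window
#' affinely to \[0, 1\] -- the standard display/preprocessing windowing
#' (defaults: level 300, width 850, a bone window).
#'
#' @param x a [ct_volume()] or a numeric array/vector of HU values.
#' @param level,width window centre and width in HU (`width > 0`).
#' @return object of the same kind as `x` with values in \[0, 1\].
#' @examples
#' window_normalize(c(-125, 87.5, 300, 725))  # 0, 0.25, 0.5, 1
#' @export
window_normalize <- function(x, level = 300, width = 850) {
  if (width <= 0) qct_abort("width must be positive", "qct_bad_argument")
  lo <- level - width / 2
  f <- function(v) pmin(pmax((v - lo) / width, 0), 1)
  if (inherits(x, "ct_volume")) {
    x$voxels <- f(x$voxels)
    x
  } else f(x)
}

#' ROI placement configuration
#'
#' @param erosion_mm in-plane erosion radius, mm; converted to per-axis voxel
#'   radii (rounded half-up) so behaviour is spacing-invariant. Must exceed
#'   the cortical shell thickness for the ROI to stay clear of cortex.
#' @param shrink initial scaling of the second-moment ellipse semi-axes.
#' @param anterior_fraction fraction of the eroded cross-section's
#'   anterior--posterior extent that is kept; the posterior remainder is
#'   excluded to avoid the basivertebral vein.
#' @param min_roi_voxels smallest acceptable ROI.
#' @param trim_fraction total fraction of extreme HU values removed before
#'   taking the median.
#' @param trim_tails `"symmetric"` (half the trim from each tail) or
#'   `"upper"` (all from the high tail).
#' @return a `roi_config` list.
#' @export
roi_config <- function(erosion_mm = 3, shrink = 0.8,
                       anterior_fraction = 2 / 3, min_roi_voxels = 50,
                       trim_fraction = 0.01,
                       trim_tails = c("symmetric", "upper")) {
  structure(list(erosion_mm = erosion_mm, shrink = shrink,
                 anterior_fraction = anterior_fraction,
                 min_roi_voxels = min_roi_voxels,
                 trim_fraction = trim_fraction,
                 trim_tails = match.arg(trim_tails)),
            class = "roi_config")
}

#' Place the elliptical trabecular ROI in a vertebra
#'
#' On the instance's mid-slab axial cross-section the body mask is eroded by
#' `erosion_mm` (clearing the cortical shell), the posterior part of the
#' eroded region is discarded (avoiding the basivertebral-vein territory),
#' and the second-moment ellipse of the remaining region -- scaled by
#' `shrink` and shrunk further until fully contained -- is extruded over the
#' instance's `body_slices` to form an elliptic-cylinder ROI covering only
#' inner trabecular bone.
#'
#' @param instance a `vertebra_instance` from [instance_label()].
#' @param config a [roi_config()].
#' @return an `elliptical_roi`: `center_mm`, `semi_axes_mm` (in-plane),
#'   `slab` (inclusive slice range), `voxel_indices` (n x 3), `n_voxels`.
#' @export
place_roi <- function(instance, config = roi_config()) {
  spacing <- instance$spacing
  orientation <- instance$orientation
  si <- anatomical_axis(orientation, "SI")
  ap <- anatomical_axis(orientation, "AP")
  if (si$axis != 3)
    qct_abort("ROI placement expects axial slices along array axis 3",
              "qct_bad_argument")
  inplane <- setdiff(1:3, si$axis)
  slab <- instance$body_slices
  mid <- as.integer(round(mean(slab)))

  co <- instance$voxel_indices
  sl <- co[co[, si$axis] == mid, inplane, drop = FALSE]
  if (!nrow(sl))
    qct_abort("instance has no voxels on its mid-slab slice",
              "qct_roi_infeasible")
  dmax <- apply(co[, inplane, drop = FALSE], 2, max)
  m <- matrix(0L, dmax[1] + 1L, dmax[2] + 1L)
  m[sl] <- 1L

  radii <- pmax(round_up_int(config$erosion_mm / spacing[inplane]), 1L)
  er <- EBImage::erode(m, ellipse_kernel(radii))
  if (!any(er > 0))
    qct_abort("erosion removed the whole cross-section: vertebra too small for erosion_mm",
              "qct_roi_infeasible")

  # keep the anterior part of the eroded region's AP extent
  idx <- which(er > 0, arr.ind = TRUE)
  ap_col <- which(inplane == ap$axis)
  ap_coord <- idx[, ap_col] * ap$sign
  cutoff <- min(ap_coord) + (1 - config$anterior_fraction) *
    (max(ap_coord) - min(ap_coord))
  keep <- ap_coord > cutoff + 1e-9
  if (!any(keep))
    qct_abort("anterior restriction left no voxels", "qct_roi_infeasible")
  region <- idx[keep, , drop = FALSE]

  # second-moment ellipse of the kept region, in mm
  sp2 <- spacing[inplane]
  pts <- sweep(region, 2, sp2, `*`)
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  C <- crossprod(cc) / nrow(cc)
  eg <- eigen(C, symmetric = TRUE)
  axes <- config$shrink * 2 * sqrt(pmax(eg$values, 1e-12))
  rot <- eg$vectors

  in_region <- array(FALSE, dim(m))
  in_region[region] <- TRUE
  ellipse_members <- function(axes) {
    all_idx <- which(m >= 0, arr.ind = TRUE)  # full grid
    p <- sweep(sweep(all_idx, 2, sp2, `*`), 2, ctr) %*% rot
    q <- (p[, 1] / axes[1])^2 + (p[, 2] / axes[2])^2
    all_idx[q <= 1, , drop = FALSE]
  }
  for (it in 1:60) {
    mem <- ellipse_members(axes)
    if (nrow(mem) && all(in_region[mem])) break
    axes <- axes * 0.95
  }
  mem <- ellipse_members(axes)
  if (!nrow(mem) || !all(in_region[mem]))
    qct_abort("could not fit a contained ellipse", "qct_roi_infeasible")

  # extrude over the body slab, restricted to the instance's own voxels
  inst_key <- paste(co[, inplane[1]], co[, inplane[2]], co[, si$axis])
  vox <- do.call(rbind, lapply(slab[1]:slab[2], function(z) {
    ok <- paste(mem[, 1], mem[, 2], z) %in% inst_key
    if (!any(ok)) return(NULL)
    out <- matrix(0L, sum(ok), 3)
    out[, inplane] <- mem[ok, , drop = FALSE]
    out[, si$axis] <- z
    out
  }))
  if (is.null(vox) || nrow(vox) < config$min_roi_voxels)
    qct_abort(sprintf("ROI has %d voxels, below min_roi_voxels = %d",
                      if (is.null(vox)) 0L else nrow(vox),
                      config$min_roi_voxels), "qct_roi_too_small")
  center <- numeric(3)
  center[inplane] <- ctr
  center[si$axis] <- (mean(slab) - 0.5) * spacing[si$axis]
  structure(list(center_mm = center, semi_axes_mm = axes,
                 slab = as.integer(slab), voxel_indices = vox,
                 n_voxels = nrow(vox), level_name = instance$level_name),
            class = "elliptical_roi")
}

#' Trimmed-median representative HU of an ROI
#'
#' Sorts the member HU values, removes the extreme `trim_fraction` of values
#' (by default split evenly between the two tails,
#' `floor(trim_fraction/2 * n)` from each) to discard outlier ossification or
#' partial-volume voxels, and returns the median of the remainder.
#'
#' @param ct a [ct_volume()].
#' @param roi an `elliptical_roi` from [place_roi()], or a bare numeric
#'   vector of HU values.
#' @param trim_fraction total trimmed fraction in \[0, 0.5).
#' @param tails `"symmetric"` or `"upper"`.
#' @return a `representative_hu` list: `value`, `n_raw`, `n_used`,
#'   `trim_fraction`.
#' @export
representative_hu <- function(ct, roi, trim_fraction = 0.01,
                              tails = c("symmetric", "upper")) {
  tails <- match.arg(tails)
  values <- if (is.numeric(roi)) roi else ct$voxels[roi$voxel_indices]
  if (!length(values)) qct_abort("empty ROI", "qct_empty_roi")
  res <- trim_median(values, trim_fraction, tails)
  structure(list(value = res$value, n_raw = res$n_raw, n_used = res$n_used,
                 trim_fraction = trim_fraction, tails = tails),
            class = "representative_hu")
}

#' Measure trabecular vBMD of L1/L2 and combine
#'
#' For each of L1 and L2 present among the instances: place the trabecular
#' ROI, compute the trimmed-median representative HU, and convert it to vBMD
#' through the protocol-matched conversion model. The combined L1-2 value is
#' the unweighted mean of the available per-vertebra values; a flag records
#' when only a single vertebra contributed.
#'
#' @param ct a [ct_volume()].
#' @param instances list from [instance_label()].
#' @param model a `conversion_model` (see [fit_conversion()]); its protocol
#'   key must match `ct$protocol`.
#' @param config a [roi_config()].
#' @return a `vbmd_result`: `per_vertebra` (named numeric),
#'   `combined_L1_2`, `single_vertebra` flag, `rois`, `rep_hu`, `failures`.
#' @export
measure_vbmd <- function(ct, instances, model, config = roi_config()) {
  if (!is.null(model$protocol) && !identical(model$protocol, ct$protocol))
    qct_abort(sprintf(
      "conversion model protocol '%s' does not match volume protocol '%s'",
      model$protocol, ct$protocol), "qct_protocol_mismatch")
  levels <- intersect(c("L1", "L2"), names(instances))
  if (!length(levels))
    qct_abort("no L1 or L2 instance available", "qct_measurement_failure")
  per <- numeric(0)
  rois <- list(); reps <- list(); failures <- character(0)
  for (lv in levels) {
    res <- tryCatch({
      roi <- place_roi(instances[[lv]], config)
      rep_hu <- representative_hu(ct, roi, config$trim_fraction,
                                  config$trim_tails)
      list(roi = roi, rep_hu = rep_hu,
           vbmd = convert_hu_to_bmd(model, rep_hu$value))
    }, qct_error = function(e) e)
    if (inherits(res, "error")) {
      failures[lv] <- conditionMessage(res)
    } else {
      per[lv] <- res$vbmd
      rois[[lv]] <- res$roi
      reps[[lv]] <- res$rep_hu
    }
  }
  if (!length(per))
    qct_abort(paste0("vBMD measurement failed for every vertebra: ",
                     paste(failures, collapse = "; ")),
              "qct_measurement_failure")
  structure(list(per_vertebra = per, combined_L1_2 = mean(per),
                 single_vertebra = length(per) < 2L, rois = rois,
                 rep_hu = reps, failures = failures,
                 model_method = model$method %||% NA_character_),
            class = "vbmd_result")
}

#' @export
print.vbmd_result <- function(x, ...) {
  cat("<vbmd_result> combined L1-2:", round(x$combined_L1_2, 2), "mg/cm^3\n")
  for (lv in names(x$per_vertebra))
    cat("  ", lv, ": ", round(x$per_vertebra[lv], 2), " mg/cm^3\n", sep = "")
  if (x$single_vertebra) cat("  (single-vertebra measurement)\n")
  invisible(x)
}

#' Rasterise an ROI to a binary array (e.g. for NIfTI export)
#'
#' @param roi an `elliptical_roi`.
#' @param dims dimensions of the target array.
#' @return integer array with 1 inside the ROI.
#' @export
roi_mask <- function(roi, dims) {
  m <- array(0L, dims)
  m[roi$voxel_indices] <- 1L
  m
}
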