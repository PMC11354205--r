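# Segmentation contract: binary lumbar mask -> ordered vertebra instances,
# first object = L1. The rule-based path stands behind the same contract a
# learned segmenter would satisfy, so one can be swapped in later.

#' Segment the lumbar spine of a CT volume
#'
#' Two paths satisfy the same contract. The `"rule_based"` path thresholds
#' bone-range HU (selecting the cortical shell) and recovers each vertebral
#' body per axial slice by a hole-sealing closing of the filled set: dilate
#' the shell to seal small apertures (e.g. where the basivertebral vein
#' pierces the posterior cortex), fill the enclosed trabecular interior,
#' then erode back; sufficiently large 3-D connected components are kept.
#' The closing radius must exceed half the widest shell aperture -- the
#' default 3 voxels covers the default 2 mm vein channel on a 1 mm grid.
#' The `"oracle"` path passes through a generator ground-truth lumbar mask.
#' Either way the result is a binary mask congruent with the volume.
#'
#' @param ct a [ct_volume()].
#' @param ground_truth a `ground_truth` object; required for the oracle path.
#' @param method `"rule_based"` or `"oracle"`.
#' @param bone_hu HU threshold selecting cortical bone (default 250).
#' @param closing_radius_vox radius (voxels) of the in-plane closing kernel.
#' @param min_component_voxels smallest 3-D component retained.
#' @return a `lumbar_mask`: list of `mask` (logical array), `source`,
#'   `spacing`, `orientation`.
#' @export
segment_lumbar <- function(ct, ground_truth = NULL,
                           method = c("rule_based", "oracle"),
                           bone_hu = 250, closing_radius_vox = 3,
                           min_component_voxels = 200) {
  method <- match.arg(method)
  if (method == "oracle") {
    if (is.null(ground_truth))
      qct_abort("oracle segmentation needs a ground_truth object",
                "qct_bad_argument")
    mask <- ground_truth$lumbar_mask > 0
    return(structure(list(mask = mask, source = "oracle",
                          spacing = ct$spacing,
                          orientation = ct$orientation),
                     class = "lumbar_mask"))
  }
  bw <- ct$voxels >= bone_hu
  if (!any(bw))
    qct_abort(sprintf("no voxel at or above %g HU: cannot segment", bone_hu),
              "qct_empty_mask")
  si <- superior_axis(ct)$axis
  if (si != 3)
    qct_abort("rule-based segmentation expects axial slices along axis 3",
              "qct_bad_argument")
  kern <- ellipse_kernel(rep(as.integer(closing_radius_vox), 2L))
  filled <- bw
  for (z in seq_len(dim(bw)[3])) {
    sl <- bw[, , z] * 1L
    if (!any(sl)) next
    # seal apertures, fill the interior, retract the boundary
    sl <- EBImage::erode(EBImage::fillHull(EBImage::dilate(sl, kern)), kern)
    filled[, , z] <- sl > 0
  }
  lab <- label_components_3d(filled)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component_voxels)
  if (!length(keep))
    qct_abort("no connected component reaches min_component_voxels",
              "qct_empty_mask")
  mask <- array(lab %in% keep, dim(lab))
  structure(list(mask = mask, source = "rule_based", spacing = ct$spacing,
                 orientation = ct$orientation),
            class = "lumbar_mask")
}

#' Dice overlap between two binary masks
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- a > 0; b <- b > 0
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Label and order vertebra instances within a lumbar mask
#'
#' Connected components (26-neighbourhood) of the mask are sorted by centroid
#' position from superior to inferior; the first object is named L1, the next
#' L2, and so on. Ties in centroid height are broken by component size
#' (larger first) and then lexicographic centroid, so the labelling is
#' deterministic and independent of component discovery order. Each
#' instance's `body_slices` is the central third of its axial extent, the
#' slab later used for ROI placement.
#'
#' @param mask a `lumbar_mask`, or a logical/integer array (then `spacing`
#'   and `orientation` must be given).
#' @param orientation,spacing grid metadata; defaults come from the
#'   `lumbar_mask`.
#' @param min_voxels components smaller than this are discarded as specks.
#' @return list of `vertebra_instance` objects, each with `level_name`,
#'   `voxel_indices` (n x 3, 1-based), `centroid_mm`, `axial_extent`
#'   (inclusive slice range along the superior axis), `body_slices`,
#'   `n_voxels`, plus the grid metadata.
#' @export
instance_label <- function(mask, orientation = NULL, spacing = NULL,
                           min_voxels = 50) {
  if (inherits(mask, "lumbar_mask")) {
    orientation <- orientation %||% mask$orientation
    spacing <- spacing %||% mask$spacing
    mask <- mask$mask
  }
  if (is.null(orientation) || is.null(spacing))
    qct_abort("orientation and spacing are required with a bare mask array",
              "qct_bad_argument")
  check_orientation(orientation)
  lab <- label_components_3d(mask > 0)
  ids <- sort(unique(lab[lab > 0L]))
  ids <- ids[tabulate(lab[lab > 0L])[ids] >= min_voxels]
  if (!length(ids))
    qct_abort("mask contains no component above min_voxels", "qct_empty_mask")
  si <- anatomical_axis(orientation, "SI")

  info <- lapply(ids, function(k) {
    idx <- which(lab == k)
    co <- arrayInd(idx, dim(lab))
    centroid_vox <- colMeans(co)
    list(idx = co, centroid_vox = centroid_vox,
         centroid_mm = (centroid_vox - 0.5) * spacing,
         extent = range(co[, si$axis]), n = nrow(co))
  })
  # pairwise overlap of axial extents > half of either -> ambiguous ordering
  for (a in seq_along(info)) for (b in seq_along(info)) {
    if (a >= b) next
    ea <- info[[a]]$extent; eb <- info[[b]]$extent
    ov <- min(ea[2], eb[2]) - max(ea[1], eb[1]) + 1
    if (ov > 0.5 * min(diff(ea) + 1, diff(eb) + 1))
      qct_abort("axial extents of two components overlap by more than half: ordering ambiguous",
                "qct_ambiguous_order")
  }
  sup_pos <- vapply(info, function(x) si$sign * x$centroid_mm[si$axis],
                    numeric(1))
  size <- vapply(info, `[[`, numeric(1), "n")
  cents <- t(vapply(info, `[[`, numeric(3), "centroid_mm"))
  ordr <- order(-sup_pos, -size, cents[, 1], cents[, 2], cents[, 3])
  out <- vector("list", length(ordr))
  for (j in seq_along(ordr)) {
    x <- info[[ordr[j]]]
    ext <- x$extent
    n_sl <- ext[2] - ext[1] + 1L
    third <- floor(n_sl / 3)
    body <- c(ext[1] + third, ext[2] - third)
    if (body[1] > body[2]) body <- rep(ext[1] + (n_sl %/% 2), 2L)
    out[[j]] <- structure(
      list(level_name = paste0("L", j), voxel_indices = x$idx,
           centroid_mm = x$centroid_mm, axial_extent = as.integer(ext),
           body_slices = as.integer(body), n_voxels = x$n,
           spacing = spacing, orientation = orientation),
      class = "vertebra_instance")
  }
  names(out) <- vapply(out, `[[`, character(1), "level_name")
  out
}

#' Export an instance table
#'
#' @param instances list from [instance_label()].
#' @return data frame with one row per vertebra (level, centroid, axial
#'   extent, voxel count).
#' @export
instance_table <- function(instances) {
  do.call(rbind, lapply(instances, function(v) data.frame(
    level = v$level_name,
    centroid_x_mm = v$centroid_mm[1], centroid_y_mm = v$centroid_mm[2],
    centroid_z_mm = v$centroid_mm[3],
    extent_lo = v$axial_extent[1], extent_hi = v$axial_extent[2],
    n_voxels = v$n_voxels, stringsAsFactors = FALSE)))
}
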