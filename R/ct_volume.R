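#' CT volume container
#'
#' A minimal in-memory representation of a CT acquisition: a 3-D array of
#' Hounsfield units plus the metadata every downstream stage needs -- voxel
#' spacing in mm, an explicit mapping from array axes to anatomical
#' directions, and an acquisition-protocol key used to pair patient scans
#' with the phantom calibration acquired under the same protocol.
#'
#' The orientation is a character vector of length 3; element `i` names the
#' anatomical direction of *increasing* array index along axis `i`, using the
#' standard one-letter codes `L`/`R` (left/right), `A`/`P`
#' (anterior/posterior), `S`/`I` (superior/inferior). Each anatomical axis
#' pair must appear exactly once, so e.g. `c("L", "A", "S")` is the analogue
#' of a NIfTI "LAS" volume.
#'
#' @param voxels 3-D numeric array of HU values (finite).
#' @param spacing numeric length-3, voxel size in mm per array axis
#'   (strictly positive).
#' @param orientation character length-3 as described above.
#' @param protocol acquisition protocol key (vendor/kVp/kernel class);
#'   calibration models are only applicable to volumes with a matching key.
#' @return an object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' superior_axis(v)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1),
                      orientation = c("L", "A", "S"),
                      protocol = "sim/120kVp/standard") {
  if (length(dim(voxels)) != 3L)
    qct_abort("voxels must be a 3-D array", "qct_bad_argument")
  if (!all(is.finite(voxels)))
    qct_abort("HU values must be finite", "qct_bad_argument")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    qct_abort("spacing must be three strictly positive numbers",
              "qct_bad_argument")
  check_orientation(orientation)
  structure(
    list(voxels = voxels, spacing = spacing,
         orientation = as.character(orientation),
         protocol = as.character(protocol)),
    class = "ct_volume")
}

check_orientation <- function(orientation) {
  ax <- c(L = "LR", R = "LR", A = "AP", P = "AP", S = "SI", I = "SI")
  if (length(orientation) != 3L || !all(orientation %in% names(ax)) ||
      length(unique(ax[orientation])) != 3L)
    qct_abort(
      "orientation must name each anatomical axis pair exactly once (e.g. c('L','A','S'))",
      "qct_bad_argument")
  invisible(orientation)
}

# which array axis runs along a given anatomical pair, and the sign of the
# anatomical "positive" direction (S, A, or R) along increasing index
anatomical_axis <- function(orientation, pair = c("SI", "AP", "LR")) {
  pair <- match.arg(pair)
  pos <- substr(pair, 1, 1)  # S, A, L
  neg <- substr(pair, 2, 2)
  axis <- which(orientation %in% c(pos, neg))
  list(axis = axis, sign = if (orientation[axis] == pos) 1 else -1)
}

#' @rdname ct_volume
#' @param x a `ct_volume` (or an orientation vector for the axis helpers).
#' @export
superior_axis <- function(x) {
  orientation <- if (inherits(x, "ct_volume")) x$orientation else x
  anatomical_axis(orientation, "SI")
}

#' @rdname ct_volume
#' @export
anterior_axis <- function(x) {
  orientation <- if (inherits(x, "ct_volume")) x$orientation else x
  anatomical_axis(orientation, "AP")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, orientation ", paste(x$orientation, collapse = ""),
      ", protocol ", x$protocol, "\n", sep = "")
  cat("  HU range [", round(min(x$voxels), 1), ", ",
      round(max(x$voxels), 1), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

# RAS-convention affine encoding spacing + axis directions (no rotation)
orientation_affine <- function(spacing, orientation) {
  dir <- c(L = -1, R = 1, P = -1, A = 1, I = -1, S = 1)
  row_of <- c(L = 1, R = 1, P = 2, A = 2, I = 3, S = 3)
  aff <- matrix(0, 4, 4)
  for (i in 1:3) aff[row_of[orientation[i]], i] <- dir[orientation[i]] * spacing[i]
  aff[4, 4] <- 1
  aff
}

#' Read and write CT volumes and masks as NIfTI
#'
#' Voxel spacing and orientation are carried in the NIfTI affine
#' (sform/qform); `read_volume()` recovers both, so a write/read round trip
#' preserves voxels, spacing and orientation exactly.
#'
#' @param x a `ct_volume`, or any 3-D array (e.g. a mask) written on the grid
#'   described by `spacing`/`orientation`.
#' @param path file path, conventionally ending in `.nii` or `.nii.gz`.
#' @param spacing,orientation grid metadata used when `x` is a bare array.
#' @param protocol protocol key attached to the volume on read.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` a
#'   `ct_volume`; `read_mask()` an integer array with `spacing`/`orientation`
#'   attributes.
#' @export
write_volume <- function(x, path, spacing = c(1, 1, 1),
                         orientation = c("L", "A", "S")) {
  if (inherits(x, "ct_volume")) {
    arr <- x$voxels; spacing <- x$spacing; orientation <- x$orientation
  } else {
    arr <- x
    check_orientation(orientation)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  aff <- orientation_affine(spacing, orientation)
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, protocol = "sim/120kVp/standard") {
  img <- RNifti::readNifti(path)
  ori <- strsplit(RNifti::orientation(img), "")[[1]]
  ct_volume(as.array(img)[, , , drop = TRUE],
            spacing = RNifti::pixdim(img)[1:3],
            orientation = ori, protocol = protocol)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)[, , , drop = TRUE]
  storage.mode(arr) <- "integer"
  attr(arr, "spacing") <- RNifti::pixdim(img)[1:3]
  attr(arr, "orientation") <- strsplit(RNifti::orientation(img), "")[[1]]
  arr
}
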