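# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed pipeline error
#'
#' All error paths in the package raise conditions subclassed under
#' `"qct_error"` so callers can distinguish, e.g., an infeasible ROI from a
#' genuinely empty segmentation mask.
#'
#' @param message error message.
#' @param class character vector of condition subclasses (prepended to
#'   `"qct_error"`).
#' @param call. logical; include the call.
#' @noRd
qct_abort <- function(message, class, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "qct_error")))
}

# round-half-up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# round-half-up to integer, used for mm -> voxel radii
round_up_int <- function(x) as.integer(floor(x + 0.5))

#' 3-D connected-component labelling (26-connectivity)
#'
#' Vectorised frontier BFS over the padded linear index space; adequate for
#' masks with up to a few hundred thousand foreground voxels.
#'
#' @param mask logical 3-D array.
#' @return integer array of the same dimensions; 0 background, components
#'   labelled 1..k in discovery order (first foreground voxel in column-major
#'   order seeds component 1).
#' @noRd
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  # linear-index offsets of the 26 neighbours in the padded array
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  offsets <- off[, 1] + off[, 2] * dp[1] + off[, 3] * dp[1] * dp[2]

  labels <- integer(prod(dp))
  fg <- which(pad)
  unvisited <- rep(TRUE, prod(dp))
  k <- 0L
  for (seed in fg) {
    if (!unvisited[seed]) next
    k <- k + 1L
    frontier <- seed
    unvisited[seed] <- FALSE
    labels[seed] <- k
    while (length(frontier)) {
      nb <- unique(rep(frontier, each = length(offsets)) +
                     rep(offsets, times = length(frontier)))
      nb <- nb[pad[nb] & unvisited[nb]]
      if (!length(nb)) break
      labels[nb] <- k
      unvisited[nb] <- FALSE
      frontier <- nb
    }
  }
  out <- array(labels, dp)[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  storage.mode(out) <- "integer"
  out
}

#' Binary elliptical (disc) kernel for 2-D morphology
#'
#' @param radii length-2 integer voxel radii along the two in-plane axes.
#' @return 0/1 matrix of size `2*radii + 1` usable as an EBImage kernel.
#' @noRd
ellipse_kernel <- function(radii) {
  radii <- pmax(as.integer(radii), 0L)
  u <- seq(-radii[1], radii[1])
  v <- seq(-radii[2], radii[2])
  a <- max(radii[1], 0.5)
  b <- max(radii[2], 0.5)
  k <- outer(u, v, function(x, y) (x / a)^2 + (y / b)^2 <= 1 + 1e-9)
  storage.mode(k) <- "integer"
  k
}

# trimmed-median core shared by representative_hu() and extract_insert_hu();
# the naive sort-drop-tails-median rule, kept free of any container logic so
# tests can call it against an independent oracle.
trim_median <- function(values, trim_fraction = 0.01,
                        tails = c("symmetric", "upper")) {
  tails <- match.arg(tails)
  n <- length(values)
  if (n == 0L) qct_abort("no values to summarise", "qct_empty_roi")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    qct_abort("trim_fraction must be in [0, 0.5)", "qct_bad_argument")
  s <- sort(values)
  if (tails == "symmetric") {
    k <- floor(trim_fraction / 2 * n)
    kept <- if (k > 0) s[(k + 1):(n - k)] else s
  } else {
    k <- floor(trim_fraction * n)
    kept <- if (k > 0) s[1:(n - k)] else s
  }
  list(value = stats::median(kept), n_raw = n, n_used = length(kept))
}
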