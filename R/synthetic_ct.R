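# Synthetic CT substrate: vertebral columns, an ESP-like calibration phantom,
# and screening cohorts with known ground truth. Everything downstream of the
# segmentation contract is exercised against volumes produced here.

#' Tissue label codes used in ground-truth masks
#'
#' Every voxel of a synthetic volume belongs to exactly one tissue class.
#' @export
TISSUE <- c(background = 0L, soft_tissue = 1L, cortical = 2L,
            trabecular = 3L, vein = 4L, calcification = 5L)

#' Specification of one synthetic vertebral body
#'
#' Vertebral bodies are modelled as elliptic cylinders stacked along the
#' superior--inferior axis: a trabecular core of known density wrapped in a
#' high-HU cortical shell (including axial end plates), with an optional
#' basivertebral-vein channel entering the posterior body at mid-height and
#' optional high-HU calcification blobs inside the core.
#'
#' @param level level name; `"L1"`, `"L2"`, ... for lumbar, `"T12"` etc. for
#'   thoracic (thoracic levels are excluded from the ground-truth lumbar
#'   mask but otherwise identical).
#' @param trabecular_density ground-truth trabecular density, mg/cm^3
#'   (non-negative).
#' @param body_radius_mm in-plane semi-axes of the body ellipse, mm; a scalar
#'   gives a circular body.
#' @param body_height_mm axial height of the body, mm.
#' @param cortical_thickness_mm thickness of the cortical shell, mm.
#' @param cortical_hu HU painted in the shell; must exceed the expected
#'   trabecular HU.
#' @param vein_channel logical; paint the basivertebral-vein channel.
#' @param vein_radius_mm,vein_hu geometry and HU of the vein channel.
#' @param n_calcifications number of calcification blobs in the core.
#' @param calcification_hu,calcification_radius_mm blob HU and radius.
#' @param center_z_mm optional explicit axial centre (mm along the
#'   superior axis); `NA` stacks bodies automatically from superior to
#'   inferior in list order.
#' @return a `vertebra_spec` list.
#' @export
vertebra_spec <- function(level = "L1", trabecular_density = 100,
                          body_radius_mm = c(17, 14), body_height_mm = 25,
                          cortical_thickness_mm = 2, cortical_hu = 600,
                          vein_channel = TRUE, vein_radius_mm = 2,
                          vein_hu = 30, n_calcifications = 0,
                          calcification_hu = 800,
                          calcification_radius_mm = 1.5,
                          center_z_mm = NA_real_) {
  if (length(body_radius_mm) == 1L) body_radius_mm <- rep(body_radius_mm, 2L)
  if (trabecular_density < 0)
    qct_abort("trabecular_density must be >= 0", "qct_bad_argument")
  if (any(body_radius_mm <= 0) || body_height_mm <= 0 ||
      cortical_thickness_mm <= 0)
    qct_abort("radii, heights and shell thickness must be positive",
              "qct_bad_argument")
  structure(list(level = level, trabecular_density = trabecular_density,
                 body_radius_mm = body_radius_mm,
                 body_height_mm = body_height_mm,
                 cortical_thickness_mm = cortical_thickness_mm,
                 cortical_hu = cortical_hu, vein_channel = vein_channel,
                 vein_radius_mm = vein_radius_mm, vein_hu = vein_hu,
                 n_calcifications = n_calcifications,
                 calcification_hu = calcification_hu,
                 calcification_radius_mm = calcification_radius_mm,
                 center_z_mm = center_z_mm),
            class = "vertebra_spec")
}

# voxel-centre coordinates (mm) along one axis
axis_mm <- function(n, spacing) (seq_len(n) - 0.5) * spacing

#' Generate a synthetic spine CT volume with ground truth
#'
#' Paints a column of vertebral bodies inside a soft-tissue cylinder on an
#' air background, following an affine ground-truth HU model
#' `HU = hu_slope * density + hu_intercept` for the trabecular core, plus
#' optional additive Gaussian noise over the whole volume. The returned
#' ground truth carries the tissue label map, the binary lumbar mask, the
#' per-vertebra instance mask (labelled 1..k from superior to inferior), the
#' true densities and the HU model -- everything needed to validate
#' segmentation, ROI placement and density recovery downstream.
#'
#' @param specs list of [vertebra_spec()] objects ordered superior to
#'   inferior (or a single spec).
#' @param hu_slope,hu_intercept affine HU ground-truth model (defaults 1, 0,
#'   i.e. HU numerically equal to density).
#' @param noise_sigma standard deviation of additive Gaussian HU noise
#'   (>= 0); applied to every voxel.
#' @param spacing voxel spacing, mm.
#' @param seed integer seed; identical seeds give bit-identical volumes.
#' @param dims_xy in-plane array dimensions.
#' @param disc_gap_mm intervertebral gap when stacking automatically.
#' @param margin_mm axial margin above/below the column.
#' @param soft_tissue_radius_mm radius of the soft-tissue cylinder.
#' @param soft_tissue_hu,background_hu HU of soft tissue and air.
#' @param orientation,protocol metadata for the returned [ct_volume()].
#' @return list with elements `volume` (a `ct_volume`) and `ground_truth`
#'   (class `ground_truth`: `tissue`, `lumbar_mask`, `instance_mask`,
#'   `density_by_instance`, `levels`, `hu_model`, plus per-instance vein and
#'   shell masks encoded in `tissue`).
#' @examples
#' sv <- generate_vertebra_volume(vertebra_spec(trabecular_density = 100),
#'                                noise_sigma = 0, seed = 1)
#' core <- sv$ground_truth$tissue == TISSUE["trabecular"]
#' mean(sv$volume$voxels[core])  # exactly 100
#' @export
generate_vertebra_volume <- function(specs, hu_slope = 1, hu_intercept = 0,
                                     noise_sigma = 0, spacing = c(1, 1, 1),
                                     seed = 1L, dims_xy = c(128, 128),
                                     disc_gap_mm = 4, margin_mm = 8,
                                     soft_tissue_radius_mm = 45,
                                     soft_tissue_hu = 40,
                                     background_hu = -1000,
                                     orientation = c("L", "A", "S"),
                                     protocol = "sim/120kVp/standard") {
  if (inherits(specs, "vertebra_spec")) specs <- list(specs)
  if (!length(specs)) qct_abort("need at least one vertebra spec",
                                "qct_bad_argument")
  if (noise_sigma < 0) qct_abort("noise_sigma must be >= 0",
                                 "qct_bad_argument")
  check_orientation(orientation)
  if (anatomical_axis(orientation, "SI")$axis != 3)
    qct_abort("the generator paints along axis 3 as superior-inferior",
              "qct_bad_argument")
  spacing <- as.numeric(spacing)

  heights <- vapply(specs, `[[`, numeric(1), "body_height_mm")
  # axial extents, mm along the superior direction (larger = more superior
  # when orientation[3] == "S"); auto-stack from the top unless explicit
  z_total <- 2 * margin_mm + sum(heights) + disc_gap_mm * (length(specs) - 1)
  explicit <- vapply(specs, function(s) is.finite(s$center_z_mm), logical(1))
  if (any(explicit) && !all(explicit))
    qct_abort("give center_z_mm for all specs or none", "qct_bad_argument")
  if (all(explicit)) {
    centers <- vapply(specs, `[[`, numeric(1), "center_z_mm")
    z_total <- max(centers + heights / 2) + margin_mm
  } else {
    top <- z_total - margin_mm
    centers <- numeric(length(specs))
    for (i in seq_along(specs)) {
      centers[i] <- top - heights[i] / 2
      top <- top - heights[i] - disc_gap_mm
    }
  }
  zlo <- centers - heights / 2
  zhi <- centers + heights / 2
  ord <- order(-centers)
  for (a in seq_along(specs)) for (b in seq_along(specs)) {
    if (a < b && zlo[a] < zhi[b] && zlo[b] < zhi[a])
      qct_abort(sprintf(
        "axial extents of specs %d (%s) and %d (%s) overlap",
        a, specs[[a]]$level, b, specs[[b]]$level), "qct_overlap")
  }
  si_sign <- anatomical_axis(orientation, "SI")$sign

  nx <- dims_xy[1]; ny <- dims_xy[2]
  nz <- as.integer(ceiling(z_total / spacing[3]))
  xs <- axis_mm(nx, spacing[1]); ys <- axis_mm(ny, spacing[2])
  zs <- axis_mm(nz, spacing[3])
  # superior-direction coordinate of each slice; flipping orientation flips it
  zsup <- if (si_sign > 0) zs else rev(zs)
  cx <- nx * spacing[1] / 2; cy <- ny * spacing[2] / 2
  ap <- anatomical_axis(orientation, "AP")
  # anterior is along axis 2 for the generator (orientation[2] in {A, P})
  if (ap$axis != 2)
    qct_abort("the generator paints along axis 2 as anterior-posterior",
              "qct_bad_argument")

  hu <- array(background_hu, c(nx, ny, nz))
  tissue <- array(TISSUE[["background"]], c(nx, ny, nz))
  instance <- array(0L, c(nx, ny, nz))

  r2_soft <- outer((xs - cx)^2, (ys - cy)^2, `+`)
  soft2d <- r2_soft <= soft_tissue_radius_mm^2
  hu[rep(soft2d, nz)] <- soft_tissue_hu
  tissue[rep(soft2d, nz)] <- TISSUE[["soft_tissue"]]

  withr::with_seed(as.integer(seed), {
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      a <- s$body_radius_mm[1]; b <- s$body_radius_mm[2]
      t <- s$cortical_thickness_mm
      if (min(a, b) <= t)
        qct_abort("body radius must exceed cortical thickness",
                  "qct_bad_argument")
      outer2d <- outer(((xs - cx) / a)^2, ((ys - cy) / b)^2, `+`) <= 1
      inner2d <- outer(((xs - cx) / (a - t))^2,
                       ((ys - cy) / (b - t))^2, `+`) <= 1
      zin <- which(zsup >= zlo[i] & zsup <= zhi[i])
      # core slices exclude the end plates (shell thickness axially too)
      zcore <- which(zsup >= zlo[i] + t & zsup <= zhi[i] - t)
      core_hu <- hu_slope * s$trabecular_density + hu_intercept
      for (z in zin) {
        sl_t <- tissue[, , z]; sl_h <- hu[, , z]; sl_i <- instance[, , z]
        shell <- outer2d & !(inner2d & (z %in% zcore))
        core <- inner2d & (z %in% zcore)
        sl_t[shell] <- TISSUE[["cortical"]]; sl_h[shell] <- s$cortical_hu
        sl_t[core] <- TISSUE[["trabecular"]]; sl_h[core] <- core_hu
        sl_i[outer2d] <- i
        tissue[, , z] <- sl_t; hu[, , z] <- sl_h; instance[, , z] <- sl_i
      }
      if (isTRUE(s$vein_channel)) {
        # cylinder along the AP axis at mid-height, from the posterior edge
        # of the body to the posterior third boundary
        # anterior-direction coordinate of each y index, centred on the body
        y_ant <- if (ap$sign > 0) ys - cy else cy - ys
        vein_mask_xz <- outer((xs - cx)^2, (zsup - centers[i])^2, `+`) <=
          s$vein_radius_mm^2
        y_sel <- which(y_ant >= -b & y_ant <= -b / 3)
        for (yi in y_sel) {
          sel <- vein_mask_xz & (tissue[, yi, ] %in%
                                   TISSUE[c("cortical", "trabecular")]) &
            instance[, yi, ] == i
          tz <- tissue[, yi, ]; hz <- hu[, yi, ]
          tz[sel] <- TISSUE[["vein"]]; hz[sel] <- s$vein_hu
          tissue[, yi, ] <- tz; hu[, yi, ] <- hz
        }
      }
      if (s$n_calcifications > 0) {
        core_idx <- which(tissue == TISSUE[["trabecular"]] & instance == i)
        if (length(core_idx)) {
          ctr <- sample(core_idx, s$n_calcifications,
                        replace = s$n_calcifications > length(core_idx))
          dims <- c(nx, ny, nz)
          coords <- arrayInd(ctr, dims)
          r <- s$calcification_radius_mm
          rv <- pmax(round_up_int(r / spacing), 1L)
          for (j in seq_len(nrow(coords))) {
            xr <- pmax(1L, coords[j, 1] - rv[1]):pmin(nx, coords[j, 1] + rv[1])
            yr <- pmax(1L, coords[j, 2] - rv[2]):pmin(ny, coords[j, 2] + rv[2])
            zr <- pmax(1L, coords[j, 3] - rv[3]):pmin(nz, coords[j, 3] + rv[3])
            for (z in zr) for (y in yr) {
              dx2 <- ((xr - coords[j, 1]) * spacing[1])^2
              d2 <- dx2 + ((y - coords[j, 2]) * spacing[2])^2 +
                ((z - coords[j, 3]) * spacing[3])^2
              sel <- xr[d2 <= r^2]
              sel <- sel[tissue[sel, y, z] == TISSUE[["trabecular"]] &
                           instance[sel, y, z] == i]
              if (length(sel)) {
                tissue[sel, y, z] <- TISSUE[["calcification"]]
                hu[sel, y, z] <- s$calcification_hu
              }
            }
          }
        }
      }
    }
    if (noise_sigma > 0)
      hu <- hu + array(stats::rnorm(length(hu), 0, noise_sigma), dim(hu))
  })

  # relabel instances 1..k in superior -> inferior order
  relabel <- integer(length(specs)); relabel[ord] <- seq_along(specs)
  instance[] <- ifelse(instance > 0L, relabel[pmax(instance, 1L)], 0L)
  storage.mode(instance) <- "integer"
  levels <- vapply(specs, `[[`, character(1), "level")[ord]
  densities <- vapply(specs, `[[`, numeric(1), "trabecular_density")[ord]
  names(densities) <- levels
  lumbar <- array(FALSE, dim(instance))
  for (k in seq_along(levels))
    if (grepl("^L", levels[k])) lumbar[instance == k] <- TRUE

  volume <- ct_volume(hu, spacing = spacing, orientation = orientation,
                      protocol = protocol)
  gt <- structure(
    list(tissue = tissue, lumbar_mask = lumbar, instance_mask = instance,
         density_by_instance = densities, levels = levels,
         hu_model = list(slope = hu_slope, intercept = hu_intercept,
                         sigma = noise_sigma)),
    class = "ground_truth")
  list(volume = volume, ground_truth = gt)
}

#' Generate a synthetic spine-phantom volume
#'
#' Emulates a European-Spine-Phantom-like calibration object: a
#' soft-tissue-equivalent elliptical body containing three parallel
#' cylindrical inserts of known, distinct bone-equivalent densities
#' (defaults 50, 100, 200 mg/cc), painted with the same affine HU model and
#' noise as the spine generator.
#'
#' @param insert_densities three distinct non-negative densities, mg/cc.
#' @param hu_slope,hu_intercept,noise_sigma ground-truth HU model as in
#'   [generate_vertebra_volume()].
#' @param n_slices number of axial slices (>= 3).
#' @param spacing voxel spacing, mm.
#' @param seed integer seed.
#' @param insert_radius_mm insert radius, mm.
#' @param orientation,protocol volume metadata.
#' @return a `phantom_scan`: list of `volume` (`ct_volume`), `insert_masks`
#'   (integer array labelling the inserts 1..3 in density order),
#'   `insert_densities`, and `protocol`.
#' @export
generate_esp_volume <- function(insert_densities = c(50, 100, 200),
                                hu_slope = 1, hu_intercept = 0,
                                noise_sigma = 0, n_slices = 20,
                                spacing = c(1, 1, 1), seed = 1L,
                                insert_radius_mm = 8,
                                orientation = c("L", "A", "S"),
                                protocol = "sim/120kVp/standard") {
  insert_densities <- as.numeric(insert_densities)
  if (length(insert_densities) != 3L || any(insert_densities < 0))
    qct_abort("need three non-negative insert densities", "qct_bad_argument")
  if (anyDuplicated(insert_densities))
    qct_abort("insert densities must be distinct (regression would be degenerate)",
              "qct_insufficient_samples")
  if (n_slices < 3) qct_abort("need at least 3 slices", "qct_bad_argument")
  check_orientation(orientation)

  nx <- 112L; ny <- 72L; nz <- as.integer(n_slices)
  xs <- axis_mm(nx, spacing[1]); ys <- axis_mm(ny, spacing[2])
  cx <- nx * spacing[1] / 2; cy <- ny * spacing[2] / 2
  body2d <- outer(((xs - cx) / 50)^2, ((ys - cy) / 30)^2, `+`) <= 1
  hu2d <- matrix(-1000, nx, ny)
  hu2d[body2d] <- 35  # soft-tissue-equivalent resin
  ins2d <- matrix(0L, nx, ny)
  offs <- c(-28, 0, 28)
  for (k in 1:3) {
    m <- outer((xs - (cx + offs[k]))^2, (ys - cy)^2, `+`) <= insert_radius_mm^2
    ins2d[m] <- k
    hu2d[m] <- hu_slope * insert_densities[k] + hu_intercept
  }
  hu <- array(rep(hu2d, nz), c(nx, ny, nz))
  insert_masks <- array(rep(ins2d, nz), c(nx, ny, nz))
  if (noise_sigma > 0)
    hu <- hu + withr::with_seed(
      as.integer(seed),
      array(stats::rnorm(length(hu), 0, noise_sigma), dim(hu)))
  structure(
    list(volume = ct_volume(hu, spacing = spacing, orientation = orientation,
                            protocol = protocol),
         insert_masks = insert_masks,
         insert_densities = insert_densities, protocol = protocol),
    class = "phantom_scan")
}

#' Age/sex vBMD reference curve for the cohort generator
#'
#' Piecewise-linear sex-specific median trabecular vBMD against age,
#' anchored at 5-year bin midpoints. The default anchors follow the shape
#' reported for Korean screening cohorts: both sexes decline with age; women
#' peak higher in their twenties but decline steeply after 50 (menopause) and
#' fall below men from the sixth decade on. Medians are non-increasing from
#' age 50 by construction.
#'
#' @return list with `male` and `female` data frames of `age` and
#'   `median_vbmd` (mg/cm^3).
#' @export
default_bmd_curve <- function() {
  age <- seq(22.5, 87.5, by = 5)
  male <- c(151, 150, 147, 145, 146, 134, 128, 122, 105, 102, 95, 84, 73, 70)
  female <- c(165, 157, 156, 154, 155, 150, 120, 107, 92, 82, 71, 65, 60, 55)
  list(male = data.frame(age = age, median_vbmd = male),
       female = data.frame(age = age, median_vbmd = female))
}

curve_median <- function(curve, sex, age) {
  tab <- curve[[sex]]
  stats::approx(tab$age, tab$median_vbmd, xout = age, rule = 2)$y
}

#' Sample a synthetic screening cohort
#'
#' Draws ages uniformly over 5-year bins spanning `age_range`, assigns sex,
#' and draws each participant's true trabecular vBMD from the sex-specific
#' age curve plus Gaussian spread. Exactly the requested numbers of
#' participants carry each exclusion flag (missing L1 coverage;
#' fracture/implant/vertebroplasty), mirroring a screening-study flowchart.
#'
#' @param n cohort size.
#' @param age_range numeric length-2, in years (minimum 20).
#' @param bmd_curve curve as from [default_bmd_curve()].
#' @param exclusion_counts integer length-2 `(missing_L1, fracture_implant)`;
#'   their sum must be < `n`.
#' @param sd_vbmd Gaussian spread around the age-curve median, mg/cm^3.
#' @param female_fraction probability a participant is female.
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @return a `cohort_spec` data frame with columns `id`, `age`, `sex`,
#'   `true_vbmd`, `flag_missing_L1`, `flag_fracture_implant`; the seed is
#'   kept in `attr(, "seed")`.
#' @export
sample_cohort <- function(n, age_range = c(20, 90),
                          bmd_curve = default_bmd_curve(),
                          exclusion_counts = c(missing_L1 = 0,
                                               fracture_implant = 0),
                          sd_vbmd = 25, female_fraction = 0.5, seed = 1L) {
  exclusion_counts <- as.integer(exclusion_counts)
  if (length(exclusion_counts) != 2L || any(exclusion_counts < 0))
    qct_abort("exclusion_counts must be two non-negative integers",
              "qct_bad_argument")
  if (sum(exclusion_counts) >= n)
    qct_abort("exclusion counts must leave at least one participant",
              "qct_bad_argument")
  if (age_range[1] < 20)
    qct_abort("ages start at 20", "qct_bad_argument")
  breaks <- seq(floor(age_range[1] / 5) * 5, ceiling(age_range[2] / 5) * 5, 5)
  withr::with_seed(as.integer(seed), {
    bin <- sample.int(length(breaks) - 1L, n, replace = TRUE)
    age <- breaks[bin] + stats::runif(n) * 5
    age <- pmin(pmax(age, age_range[1]), age_range[2] - 1e-9)
    sex <- ifelse(stats::runif(n) < female_fraction, "female", "male")
    med <- ifelse(sex == "female",
                  curve_median(bmd_curve, "female", age),
                  curve_median(bmd_curve, "male", age))
    vbmd <- pmax(med + stats::rnorm(n, 0, sd_vbmd), 5)
    flagged <- sample.int(n, sum(exclusion_counts))
  })
  flag_missing <- logical(n)
  flag_fracture <- logical(n)
  if (exclusion_counts[1] > 0)
    flag_missing[flagged[seq_len(exclusion_counts[1])]] <- TRUE
  if (exclusion_counts[2] > 0)
    flag_fracture[flagged[exclusion_counts[1] + seq_len(exclusion_counts[2])]] <- TRUE
  out <- data.frame(
    id = sprintf("P%05d", seq_len(n)), age = age, sex = sex,
    true_vbmd = vbmd, flag_missing_L1 = flag_missing,
    flag_fracture_implant = flag_fracture, stringsAsFactors = FALSE)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("cohort_spec", "data.frame")
  out
}

#' Read and write cohort tables as CSV
#'
#' @param cohort a cohort data frame (e.g. from [sample_cohort()]).
#' @param path CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   `cohort_spec` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (fl in intersect(c("flag_missing_L1", "flag_fracture_implant"),
                       names(out)))
    out[[fl]] <- as.logical(out[[fl]])
  class(out) <- c("cohort_spec", "data.frame")
  out
}
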