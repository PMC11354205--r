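---
title: "Opportunistic QCT screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opportunistic QCT screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qctscreen)
```

## The screening problem

Chest CT acquired for lung-cancer screening incidentally covers the upper
lumbar vertebrae. Because CT attenuation (Hounsfield units, HU) of
trabecular bone rises with its mineral content, such scans can be reused --
at no extra dose or cost -- to measure trabecular volumetric bone mineral
density (vBMD, mg/cm³) of L1 and L2 and screen for osteoporosis. qctscreen
implements that pipeline end to end:

1. **Segmentation contract**: a binary lumbar mask is split into 3-D
   connected components, ordered superior → inferior; the first object is
   L1, the next L2.
2. **ROI placement**: within each vertebra's central axial slab, the body
   cross-section is eroded to clear the cortical shell, the posterior part
   is excluded to avoid the basivertebral vein, and a contained
   second-moment ellipse is extruded into an elliptic-cylinder ROI over
   inner trabecular bone.
3. **Representative HU**: the ROI's HU distribution is trimmed of its
   extreme 1% (guarding against focal calcification and partial-volume
   voxels) and summarised by the median.
4. **Calibration**: a spine phantom with inserts of known density
   (50/100/200 mg/cc) scanned under the same protocol yields per-insert
   per-slice HU samples; six regression families are fitted (BMD as a
   function of HU) and the lowest-RMSE equation is selected, provided its
   RMSE does not exceed 5.0 mg/cc -- otherwise the phantom must be
   re-acquired.
5. **Classification and reporting**: vBMD is classified by the ACR QCT
   criteria (osteoporosis < 80, osteopenia 80–120, normal > 120 mg/cm³) and
   summarised as age/sex-stratified median (IQR) tables plus crude and
   age-standardized prevalence among participants aged 50 and over.

A trained neural segmenter is deliberately *not* part of the package: the
`segment_lumbar()` contract isolates it, and a rule-based reference
implementation (HU threshold + hole-sealing closing + component filtering)
stands behind the same interface so that every downstream stage is fully
testable. A learned segmenter can be dropped in later without touching the
rest of the pipeline.

## The synthetic-data generator

No patient scans ship with the package. Instead `generate_vertebra_volume()`
paints vertebral bodies as elliptic cylinders stacked along the
superior–inferior axis inside a soft-tissue cylinder on an air background,
with voxel-level ground truth (tissue label map, instance mask, true
densities, HU model). The trabecular core follows the affine ground-truth
model

$$\mathrm{HU} = a \cdot \mathrm{BMD} + b + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2),$$

with defaults \(a = 1, b = 0\) -- the same linear family the calibration
must recover, which makes recovery tests exact in expectation. Defaults
(chosen once, as plausible adult lumbar anatomy at screening dose):

| parameter | default | note |
|---|---|---|
| body semi-axes | 17 × 14 mm | in-plane ellipse |
| body height | 25 mm | disc gap 4 mm |
| cortical shell | 2 mm at 600 HU | includes axial end plates |
| vein channel | r = 2 mm at 30 HU | enters the posterior body at mid-height |
| calcification blobs | r = 1.5 mm at 800 HU | optional, inside the core |
| soft tissue / air | 40 / −1000 HU | |
| grid | 1 mm isotropic, 128 × 128 in-plane | orientation stored explicitly |

`generate_esp_volume()` builds the calibration phantom analogue: three
cylindrical inserts of distinct known densities (default 50/100/200 mg/cc)
in a soft-tissue-equivalent body. `sample_cohort()` draws a screening
cohort: ages uniform within 5-year bins, sex-specific true vBMD from a
piecewise-linear median curve anchored at published age/sex medians for a
Korean screening population (women peak higher in their twenties, decline
steeply after 50 and fall below men thereafter; the anchors are monotonised
from age 50 so the median decline holds by construction), plus Gaussian
spread of SD 25 mg/cm³, matching the reported IQR widths of roughly 40
mg/cm³.

What the generator does *not* emulate -- and hence what passing tests do
not show about real data: posterior elements, ribs and anatomical shape
variation; scanner physics (beam hardening, scatter, kernel-dependent
noise texture); contrast media; fractures and degenerative deformity. The
generator validates the *measurement logic*; claims about clinical accuracy
require real scans and a validated segmenter.

## Numerical choices

* **Trim-tail allocation.** "Remove the extreme 1%" does not say one- or
  two-tailed. Default: symmetric, `floor(0.005 n)` per tail -- the median
  is insensitive to the choice, and symmetric trimming also guards against
  low-HU vein and partial-volume voxels. A one-tailed (upper) mode is
  available via `roi_config(trim_tails = "upper")`. Trim counts use
  `floor`.
* **ROI geometry.** Erosion radius is specified in mm (3 mm default,
  exceeding the 2 mm shell) and converted per-axis to voxels with half-up
  rounding, so behaviour is spacing-invariant. The anterior fraction kept
  is 2/3; the second-moment ellipse is scaled by 0.8 and then shrunk
  multiplicatively (factor 0.95) until every member voxel lies inside the
  eroded anterior region; the slab is the central third of the body's
  axial extent (a 3-D slab, consistent with a *volumetric* BMD; extent
  configurable).
* **Hole-sealing closing.** A plain morphological closing of the
  thresholded shell cannot bridge the vein aperture: the bridged web is
  thinner than the structuring element and erodes away again. The
  rule-based segmenter therefore dilates, fills enclosed holes, then
  erodes -- a closing of the *filled* set -- with default radius 3 voxels,
  just over half the default vein-channel diameter on a 1 mm grid.
* **Connectivity and ordering.** Components use 26-connectivity (least
  fragmenting; disc gaps guarantee separation). Ordering ties are broken
  by size, then lexicographic centroid, so labelling never depends on
  discovery order. Axially overlapping components (> half of either
  extent) raise an ambiguous-ordering error rather than guessing.
* **Calibration families.** The six candidates are linear, quadratic,
  power, logarithmic, exponential and robust (Theil–Sen median-of-pairwise-
  slopes) linear -- the standard calibration families. Log-family models
  are fitted by least squares in log space and carry a positive HU domain.
  RMSE is computed in-sample over per-insert per-slice rows (so quadratic
  cannot trivially interpolate three aggregate means, and RMSE is a
  meaningful noise measure). Non-monotone candidates lose RMSE ties; the
  5.0 mg/cc recalibration bound is strict ("exceeded" means > 5.0).
  Models are keyed by acquisition protocol; applying a model to a volume
  with a different protocol key is an error, never a silent fallback.
* **Classification boundaries.** The printed criteria ("< 80", "80–120",
  "> 120") place both 80 and 120 in osteopenia; encoded exactly so.
  Quartiles use the linear-interpolation convention (R type 7, recorded in
  the table attributes). Display rounding is half-up to one decimal;
  internal values stay unrounded.
* **Indices.** Voxel indices are 1-based and slice ranges are inclusive,
  following R convention throughout.

## Worked example

```{r example, eval = FALSE}
# calibrate from a simulated phantom (sigma = 5 HU, 20 slices)
ph <- generate_esp_volume(noise_sigma = 5, n_slices = 20, seed = 42)
model <- select_model(fit_conversion(extract_insert_hu(ph)))

# measure a simulated patient with true density 100 mg/cm^3
sv <- generate_vertebra_volume(
  list(vertebra_spec("L1", 100), vertebra_spec("L2", 100)),
  noise_sigma = 10, seed = 1)
inst <- instance_label(segment_lumbar(sv$volume))
measure_vbmd(sv$volume, inst, model)

# or run the whole pipeline, cohort included
res <- run_pipeline(pipeline_config(tempfile("qct-demo"), seed = 1,
                                    n_participants = 30))
res$report
```

Problem sizes used by the test-suite and demo runs -- 20-slice phantoms,
one or two vertebrae per simulated scan at 1 mm spacing, cohorts of a few
dozen (imaged) to a few thousand (table-only) participants -- were chosen
so each stage is exercised at full fidelity while a complete run stays
interactive.

## Standardization and the standard population

Direct age standardization computes \(\sum_b w_b p_b\) over 5-year bins
\(b\), with \(w_b\) a reference population's age-bin weights and \(p_b\)
the observed per-bin prevalence. Two identities pin the implementation
down: weights equal to the cohort's own bin shares reproduce the crude
rate exactly, and uniform prevalence is a fixed point under any weights.
Bins without observed prevalence are dropped and the remaining weights
renormalized, with a warning. The real reference distribution used in the
original cohort analysis (a national census table) is external data and is
not shipped; a clearly-labelled **synthetic** standard population
(`inst/extdata/standard_population_synthetic.csv`, bins 50–54 … 85+) is
bundled, and every report names the standard it used.

## Known limitations

* The rule-based segmenter is validated on synthetic geometry only; on
  real scans it would also pick up ribs, posterior elements and the
  sternum, and a trained model is required.
* Single-energy QCT cannot separate marrow fat from mineral; the package
  inherits that bias structure but does not model it.
* Cortical BMD, per-voxel BMD maps, fracture detection and DXA comparison
  are out of scope.
* Prevalence estimates carry no confidence intervals; the report reproduces
  point estimates only.
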