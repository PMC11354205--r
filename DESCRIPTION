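Package: qctscreen
Title: Opportunistic QCT Osteoporosis Screening from CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for opportunistic quantitative computed
    tomography (QCT) screening of osteoporosis: synthetic CT and calibration
    phantom generation with voxel-level ground truth, rule-based lumbar
    vertebra segmentation and instance labelling, erosion-derived elliptical
    trabecular regions of interest with trimmed-median representative
    Hounsfield units, phantom-based HU-to-BMD calibration over six candidate
    regression families with RMSE-based model selection, ACR QCT diagnostic
    classification, and age/sex-stratified crude and age-standardized
    prevalence reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
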