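Package: ctcomp
Title: Whole-Body CT Body Composition: Calibrated Segmentation and
    Single-Slice Prediction of Tissue Volumes and Masses
Version: 0.1.0
Authors@R:
    person("ctcomp", "maintainers", email = "ctcomp@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic measurement of whole-body adipose-tissue (AT)
    and lean-tissue (LT) volumes from CT volumes, and prediction of total
    body AT and LT volumes and masses from single axial slices. Provides
    per-subject Hounsfield-unit cutoff calibration from eight line-profile
    histograms, 3x3x3 median denoising, threshold segmentation and
    volumetry, a registry of published single-slice prediction equations,
    OLS model fitting with residual diagnostics, a linear epsilon-SVR
    multislice predictor with leave-one-out cross-validation, inter-rater
    agreement statistics (ICC, Bland-Altman), synthetic CT phantoms and
    cohort tables with known ground truth, and a command-line pipeline.
    Includes minimal NIfTI-1 and DICOM readers for HU volumes with voxel
    geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
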