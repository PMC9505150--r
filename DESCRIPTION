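Package: dosiomics
Title: Dosiomic and Radiomic Texture Analysis for Radiotherapy Response Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting local failure after stereotactic prostate
    re-irradiation from texture analysis of CT, PET-SUV and biologically
    effective dose (BED) distributions inside the gross tumour volume.
    Implements the full image-processing chain (SUV and linear-quadratic BED
    conversion, crossing-number contour rasterization, trilinear resampling to
    1 mm isotropic voxels, fixed-bin-number discretization), a fixed
    380-feature radiomic catalogue following Image Biomarker Standardisation
    Initiative conventions (shape, intensity statistics, histogram, GLCM,
    GLRLM, GLSZM, NGTDM, NGLDM), and a leakage-safe ensemble learning stack
    (ADASYN oversampling, regularized neighbourhood component analysis
    feature weighting, RobustBoost-aggregated shallow decision trees)
    evaluated by repeated stratified cross-validation. A synthetic phantom
    cohort generator with a planted dose-texture outcome signal supports
    development and validation in the absence of shareable patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
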