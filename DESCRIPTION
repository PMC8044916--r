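Package: nactrad
Title: Longitudinal DCE-MRI Radiomics for Early Prediction of Neoadjuvant
    Chemotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end delta-radiomics analysis of paired baseline and
    early-treatment dynamic contrast-enhanced MRI of breast tumors.
    Provides NIfTI image handling, a simplified multiplicative bias-field
    corrector, spatial fuzzy C-means tumor segmentation, multi-resolution
    Gaussian-regularized demons registration with Jacobian determinant
    maps, an IBSI-style 102-feature radiomics engine (shape, first-order,
    GLCM, GLRLM, GLSZM, GLDM), relative net feature change (deltaRAD),
    SVM-RFE feature ranking with cross-validated grid search, ROC/Youden
    operating-point evaluation with paired AUC comparison, cohort
    filtering and group-comparison statistics, and a synthetic-cohort
    generator with ground-truth deformation for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    e1071,
    pROC,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
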