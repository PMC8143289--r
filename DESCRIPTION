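Package: locrad
Title: Local First-Order Radiomics for Classifying Prostate Lesions on
    High b-Value Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting clinically significant prostate cancer
    from lesion regions of interest on high b-value diffusion-weighted MR
    volumes (or coregistered ADC maps). Implements sliding-window local
    first-order texture statistics summarized into an 84-feature radiomic
    vector per patient, feature-couple selection by LASSO, pairwise
    correlation filtering and Wilcoxon rank-sum tests with Holm-Bonferroni
    correction, a class-weighted linear support-vector-machine workflow
    with repeated stratified cross-validation and an overfitting filter
    cascade, and ROC/Youden-index evaluation with bootstrap confidence
    intervals. A synthetic phantom-cohort generator with planted lesion
    heterogeneity and asymmetry effects makes the full pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
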