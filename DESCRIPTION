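Package: habstas
Title: Intratumoral Habitat and Peritumoral CT Radiomics for Predicting
    Spread Through Air Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for CT habitat radiomics analysis of small
    solid lung adenocarcinomas, aimed at preoperative prediction of spread
    through air spaces (STAS). Provides isotropic resampling and lung-window
    normalisation of CT volumes, spacing-aware peritumoral ring morphology at
    1/3/5 mm, per-voxel local-feature maps with K-means habitat subregion
    clustering selected by the Calinski-Harabasz index, IBSI-style shape,
    first-order and texture feature extraction, a multi-stage feature
    selection cascade (ICC, Mann-Whitney, Pearson pruning, mRMR, LASSO),
    multi-algorithm model training with stacked fusion, and a full evaluation
    battery (DeLong AUC inference, calibration, decision curves, logistic
    regression reports). A phantom-cohort generator with known habitat
    structure and a known label-generating model makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    glmnet,
    ranger,
    xgboost,
    nnet,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
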