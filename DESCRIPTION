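Package: usradiomics
Title: 2D Ultrasound Radiomics, Screening and Classification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end 2D radiomics analysis for greyscale ultrasound
    regions of interest: a speckle phantom simulator for synthetic cohorts,
    minimal DICOM image/mask input-output, a 232-feature catalog (first-order,
    morphology, grey-level co-occurrence/run-length/size-zone/distance-zone
    texture matrices and box-counting fractal dimensions), Pearson-correlation
    redundancy pruning with Wilcoxon-Mann-Whitney univariate screening, and
    four patient-grouped classification strategies including a Cohen-Kappa /
    Youden-index forward feature-selection wrapper, gradient-boosted trees
    with grid search, and a genetic pipeline search.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    e1071,
    xgboost,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    caret,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
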