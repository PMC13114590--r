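Package: habitomics
Title: Habitat Radiomics Pipeline for Pleural Invasion Prediction on Low-Dose CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Habitat-based radiomics analysis of subpleural lung nodules on
    low-dose CT. Generates synthetic nodule phantom cohorts with ground-truth
    subregions and batch structure, preprocesses volumes (isotropic resampling,
    lung-window clipping, z-normalization, fixed-bin-count discretization),
    partitions lesions into habitats via 3D SLIC superpixels and frozen
    K-means cluster models with Davies-Bouldin model selection, extracts
    IBSI-style texture features (first-order, shape, GLCM, GLRLM, GLSZM, GLDM,
    NGTDM) per lesion and per habitat, harmonizes feature tables across
    scanner batches with empirical-Bayes location-scale adjustment, builds
    logistic signatures through a Spearman / Mann-Whitney / mRMR / LASSO /
    backward-elimination selection chain, and evaluates them with DeLong AUC
    comparison, calibration, Brier scores, decision-curve analysis and
    intraclass correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    randomForest,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    sva
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
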