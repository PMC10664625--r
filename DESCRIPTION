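Package: tensorflavor
Title: Multi-Flavored Feature Extraction for Prostate mpMRI Grade Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multi-flavored ("tensor") feature-extraction pipeline
    for prostate cancer grade-group classification from multiparametric MRI.
    Four modality regions of interest (T2W-transverse, T2W-sagittal, DWI, ADC)
    are fused pairwise with eight pixel-level fusion algorithms (Laplacian and
    ratio-of-low-pass pyramids, decimated and stationary wavelets, a dual-tree
    complex wavelet, an FFT directional multiscale transform, weighted
    averaging and PCA weighting) into a 52-flavor image stack per patient.
    From every flavor the package extracts 107 radiomics features in seven
    classes and 7200 deep features from the bottleneck of a convolutional
    autoencoder, assembles five feature sets, runs a fold-safe preprocessing
    chain (SMOTE, standardization, PCA, correlation filtering, LASSO), and
    evaluates nine classifiers with stratified cross-validation (balanced
    accuracy, ROC/AUC). A phantom module generates synthetic lesion cohorts
    with the study geometry so the whole pipeline is testable offline.
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
    e1071,
    ranger,
    rpart,
    xgboost,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
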