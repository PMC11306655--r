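Package: pdfe
Title: Patch-Based Deep Feature Engineering for Two-Class Brain CT Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a patch-based deep feature engineering pipeline for
    two-class grayscale image classification, aimed at screening non-contrast
    head CT slices for large versus small cerebral vessel occlusion. Images
    are resized to a fixed grid, tiled into 16x16 patches, and deep features
    are extracted from the raw image and every patch with a frozen
    AlexNet-architecture backbone (fc6 and fc7 activations) or a seeded
    random-projection extractor. Fused features are ranked by neighborhood
    component analysis (NCA) and the best top-k prefix is chosen by an
    iterative selector (INCA) scored with cross-validated 1-NN loss. Final
    evaluation uses a 1-NN Euclidean classifier under stratified tenfold
    cross-validation, with a nine-classifier benchmark harness and a seeded
    synthetic phantom generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    randomForest,
    nnet,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
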