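Package: mrsinet
Title: Hierarchical 1D Convolutional Networks for Nosologic Mapping of
    MRSI Therapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tracks glioblastoma therapy response from magnetic resonance
    spectroscopic imaging (MRSI) grids by classifying every voxel spectrum
    with a two-stage cascade of one-dimensional convolutional neural
    networks: normal parenchyma versus tumour first, then responding versus
    unresponsive tumour.  Includes spectral windowing and unit-length (UL2)
    normalisation, subject-level train/test splitting, SMOTE class
    balancing, four tuned baseline classifier families, Grad-CAM relevance
    maps for spectra, nosologic colour-coded map construction, multiclass
    Dice evaluation, and a synthetic MRSI phantom generator so the whole
    pipeline runs without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    glmnet,
    e1071,
    ranger,
    xgboost
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
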