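Package: leafspec
Title: Multi-Trait Estimation of Leaf Biochemistry from Hyperspectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating leaf biochemical and
    nutritional traits (nitrogen, phosphorus, potassium, calcium, magnesium,
    micronutrients, pigments, equivalent water thickness, leaf mass per area,
    and a leaf structural parameter) from 400-2500 nm leaf reflectance
    spectra. Includes spectral standardisation and Savitzky-Golay smoothing,
    correlation-based adjacent-band merging, variance-threshold PCA, bias
    calibration of radiative-transfer-model trait estimates, a convolutional
    imputer for missing trait labels with reliability-based sample weighting,
    single- and multi-trait CNN-LSTM regressors with a Transformer baseline
    (built on a compact internal neural-network engine), k-nearest-neighbour
    spectral dissimilarity for applicability-domain uncertainty, and a
    synthetic-data generator that emulates a multi-season grapevine leaf
    dataset so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    signal,
    MASS,
    ranger,
    xgboost,
    e1071,
    glmnet,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
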