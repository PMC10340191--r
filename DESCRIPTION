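Package: hrccnet
Title: High-Resolution Network with Dynamic Convolution and Coordinate
    Attention for Multi-Label Chest Radiograph Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds, trains, profiles and evaluates a parallel
    multi-resolution convolutional network for multi-label chest X-ray
    classification. The network keeps a high-resolution feature stream
    throughout and repeatedly exchanges information with progressively
    lower-resolution, wider streams. Blocks can use conditionally
    parameterized (dynamic) convolution, in which a per-sample routing
    function mixes several expert kernels, and coordinate attention,
    which gates features with direction-aware pooled summaries. Training
    minimises a focal loss, optionally reweighted per class by the
    inverse of the previous epoch's per-class accuracy. The package
    includes label readers for the two common chest-radiograph CSV
    dialects, uncertainty-label policies, patient-aware dataset
    splitting, a synthetic multi-label lesion-image generator, per-class
    ROC/AUC and confusion metrics, activation heatmaps, and an analytic
    parameter/FLOP profiler. The numerical core (convolution,
    backpropagation, Adam) is implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
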