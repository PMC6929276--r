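Package: secnn
Title: Super-Enhancer Calling and Convolutional Neural Network Prediction
Version: 0.1.0
Authors@R: person("Maintainer", "secnn", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: An end-to-end workflow for predicting super-enhancers from
    chromatin features. Quantifies ChIP-seq read densities over enhancer
    intervals, calls super-enhancers ROSE-style from Mediator (Med1) signal
    (12.5 kb stitching, ranked-signal elbow cutoff), assembles a 36-column
    feature matrix (signal densities, sequence composition, conservation,
    motif binding affinities), trains small 1-D convolutional classifiers
    with 2-4 convolutional layers by backpropagation and Adam, evaluates
    them (precision/recall/F1/accuracy, ROC/AUC, stratified cross-validation,
    hyper-parameter grid search), and ranks features by point-biserial
    Pearson correlation. Includes seeded simulators for reads with planted
    peaks and for class-imbalanced feature tables, so the whole pipeline is
    testable at desk scale, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
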