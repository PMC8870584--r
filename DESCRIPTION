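Package: parkwave
Title: Wavelet Scalogram Deep Learning for Resting-State EEG Parkinson's
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens resting-state electroencephalography (EEG) for
    Parkinson's disease with a continuous Morlet wavelet pipeline: per-channel
    scalograms are min-max scaled, segmented into 128x128 grayscale tiles, and
    classified by a 20-layer convolutional neural network trained with
    stochastic gradient descent. Evaluation is subject-wise k-fold
    cross-validation with accuracy, sensitivity, specificity, ROC/AUC and
    quadratic weighted kappa, for two-class (healthy control versus patients
    off medication, off versus on medication) and three-class experiments.
    Grad-CAM heat maps expose the time-scale regions driving each prediction.
    Includes a synthetic multichannel EEG cohort generator with
    class-dependent oscillatory band power over a 1/f background, readers for
    BrainVision and delimited-matrix recordings, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    grDevices,
    jsonlite,
    png,
    stats,
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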