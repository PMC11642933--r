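Package: namts
Title: Neural Additive Models for Multichannel Physiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretable prediction of individual neonatal apnea and
    hypopnea events from multichannel polysomnography. Implements a neural
    additive model whose per-modality subnetworks are small 1D fully
    convolutional networks, yielding per-modality additive contributions and
    time-resolved activation maps alongside each prediction. Includes the
    full pipeline: recording and annotation I/O (EDF and a plain-text
    fixture dialect), a synthetic neonatal polysomnography cohort generator
    with planted pre-event signatures, 30-second window extraction with
    event masking, anti-aliased decimation and per-window normalization,
    24 engineered spectral and moment features for baseline classifiers,
    patient-based leave-one-out cross-validation with nested hyperparameter
    selection, permutation tests of AuROC and Wilcoxon signed-rank model
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    signal,
    jsonlite,
    yaml,
    glmnet,
    nnet
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
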