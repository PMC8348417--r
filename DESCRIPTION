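Package: eegentropy
Title: Entropy-Based EEG Emotion Recognition Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for EEG-based emotion recognition from
    short signal windows. Generates synthetic eight-channel EEG sessions with
    controllable class-dependent signal complexity, extracts six entropy
    measures (permutation, singular-value-decomposition, approximate, sample,
    spectral and continuous-wavelet entropy) from sliding windows, selects
    informative electrodes by one-way ANOVA with Tukey HSD post-hoc tests,
    and evaluates support-vector-machine, multi-layer-perceptron and
    one-dimensional convolutional-network classifiers under stratified
    5-fold and leave-one-subject-out cross-validation. Includes Welch
    power-spectral-density utilities for resting-state alpha-peak checks
    and EDF/delimited-text recording input and output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    e1071,
    pROC,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
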