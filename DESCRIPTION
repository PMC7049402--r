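Package: hrvmodal
Title: Multimodal Heart Rate Variability Features for Congestive Heart
    Failure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts multimodal features from RR-interval (tachogram)
    series -- time-domain (SDANN, SDNN, SDSD, RMSSD), frequency-domain
    band powers from a Lomb-Scargle or resample-plus-Welch spectrum
    (TP, ULF, VLF, LF, HF, LF/HF), statistical moments, and nonlinear
    complexity measures (approximate entropy, KD-tree accelerated
    sample entropy, and Shannon / log-energy / threshold / sure / norm
    wavelet entropy functionals) -- and evaluates a battery of
    classifiers (decision trees, support vector machines, k-nearest
    neighbours, ensembles) under stratified 10-fold cross-validation to
    separate normal sinus rhythm from congestive heart failure
    subjects. Includes a synthetic tachogram cohort generator so the
    full pipeline is testable without clinical recordings, and
    performance reporting (sensitivity, specificity, predictive
    values, total accuracy, rank-based AUC, normal-theory confidence
    intervals, per-feature Welch tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    MASS,
    rpart,
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
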