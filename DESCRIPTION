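Package: cardiodyn
Title: Nonlinear Dynamics Modelling of Phone-Collected Heart Sound Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for phonocardiogram recordings collected with
    unmodified mobile phones. Extracts nonlinear-dynamics features (maximal
    Lyapunov exponent, correlation dimension, sample and Renyi entropy, Hurst
    exponent, Higuchi and Katz fractal dimensions) and classical acoustic
    features (Welch power spectrum, cepstrum, band powers) from heart-sound
    audio, screens recordings for low-dimensional chaos, builds unweighted
    signed-sum predictors by simulated-annealing search under a conditional
    entropy objective, maps them to echocardiographic outcomes with logistic
    or linear models fitted on a tuning set only, and reports diagnostic
    performance (confusion counts, sensitivity, specificity, accuracy, AUC).
    Includes a synthetic-cohort generator with benchmark chaotic and
    stochastic signals, heart-sound synthesis with severity-linked murmurs,
    cluster-stratified train/test splitting with a test-set firewall, and
    events-per-variable sample-size arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    deSolve,
    jsonlite,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
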