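Package: msissa
Title: Markov-Switching Integrated Step-Selection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint estimation of behavioural states, movement kernels and
    habitat selection from animal tracking data via a Markov-switching
    conditional logistic regression (the hidden Markov integrated
    step-selection analysis, HMM-iSSA). Includes simulation of Gaussian
    random field habitat covariates and of state-switching movement tracks,
    case-control data construction with parametric proposal distributions,
    forward-algorithm likelihood evaluation with constrained multi-start
    maximum likelihood, Viterbi state decoding, Wald inference and
    AIC/BIC model selection, plus the two competitor analyses (plain iSSA
    and the classification-based two-step TS-iSSA) and a simulation-study
    runner comparing the three.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
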