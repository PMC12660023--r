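Package: lmmni
Title: Latent Markov Models for Noninvariant Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and decoding of latent Markov (hidden Markov) models for
    mixed-type longitudinal assessment data in which the measurement process may
    differ across measurement events (items). Provides per-item emission models for
    nominal, ordinal, continuous and count indicators, maximum-likelihood estimation
    by an expectation-maximization algorithm built on scaled forward-backward
    recursions, Viterbi state decoding, numerical-Hessian standard errors,
    information criteria, a measurement-invariant constrained variant, and a Monte
    Carlo simulation and evaluation engine for parameter-recovery and cross-fit
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    optparse,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
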