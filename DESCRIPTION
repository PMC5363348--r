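Package: markovmiss
Title: Continuous-Time Markov Models for Longitudinal Binary Outcomes
    with Informative Dropout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a continuous-time three-state Markov ("illness-death")
    model to longitudinal dichotomous outcomes from randomized trials in
    which patients may drop out. States are nonresponse, response and an
    absorbing dropout state; closed-form transition probabilities, a
    multinomial transition likelihood over panel-observed visits, and
    both maximum-likelihood and Bayesian (adaptive Metropolis) fitting
    with patient-level random effects and covariates are provided.
    Derived estimands include time-dependent odds ratios, transition
    rate ratios, expected time in state, and probabilities of dropout
    with or without prior response. A four-state hidden-state extension
    encodes MCAR, MAR, MNAR and LOCF-like missingness scenarios for
    sensitivity analysis of the unobserved outcomes of dropouts. An
    exact trajectory simulator generates synthetic trial data and
    serves as a Monte-Carlo oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    coda,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
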