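Package: zolpitox
Title: Population Pharmacokinetic Simulation and Estimation for Zolpidem Overdose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates plasma zolpidem concentration-time profiles after
    therapeutic doses and overdoses using a one-compartment population
    pharmacokinetic model with first-order absorption, absorption lag time,
    correlated lognormal interindividual variability, and proportional
    residual error. Provides Monte Carlo percentile bands, duration-above-
    threshold summaries for the toxic, comatose, and fatal concentration
    ranges, non-compartmental analysis (linear-up/log-down AUC, terminal
    slope), and a first-order conditional estimation with interaction
    (FOCE-I) engine with likelihood-ratio testing, bootstrap confidence
    intervals, residual diagnostics, and visual predictive checks. Includes
    a synthetic study generator for a single-oral-dose rich-sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
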