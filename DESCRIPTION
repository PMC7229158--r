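Package: burstfit
Title: Transcriptional Burst Kinetics from Single-Cell mRNA Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying transcriptional bursting from single-cell
    mRNA copy-number data (e.g. smFISH counts). Implements a three-state
    promoter model (deep inactive, primed inactive, active) whose steady-state
    mRNA distribution is a zero-inflated negative binomial, exact Gillespie
    simulation of the underlying kinetics, descriptive noise statistics
    (CV-squared and Fano factor with bootstrap standard errors), Bayesian
    inference of burst size, burst frequency and deep-inactive occupancy by
    Metropolis-Hastings MCMC, and closed-form noise/Fano scaling laws that
    distinguish burst-size from burst-frequency regulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
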