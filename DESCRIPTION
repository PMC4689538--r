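Package: sclineage
Title: Stochastic Two-Compartment Stem-Cell Lineage Dynamics and Control-Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the balance of symmetric and asymmetric
    stem-cell divisions shapes homeostasis in a two-compartment lineage of
    stem and differentiated cells. Provides feedback control-network
    definitions (division rate, symmetric-division probability,
    differentiation probability, death rate, optional exogenous stem-cell
    influx), steady-state solvers and mean-field integration, linear-noise-
    approximation variances with stability conditions and critical division
    symmetry, enumeration and classification of minimal control systems, and
    a discrete stochastic simulator with micro-injury and influx
    perturbations, replicate sweeps, and CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
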