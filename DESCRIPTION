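Package: kincompass
Title: Ensemble-Based Experiment Design for Multiphase Chemical Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical design-of-experiments toolkit for kinetic models with
    poorly constrained parameters. Represents the solution space of a kinetic
    model as a fit ensemble obtained by rejection sampling against decay data
    (approximate Bayesian computation), and ranks candidate experimental
    conditions by their potential to constrain that ensemble using
    ensemble-spread and parameter-constraint-potential metrics. Ships a
    multi-layer reactive-diffusion flux model of ozone uptake into oleic acid
    aerosol particles, a feed-forward neural-network surrogate of it, an
    iterative simulated-experiment study harness, and an application of the
    ensemble-spread metric to QSAR prediction committees over enumerated
    substituted quinones.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    yaml,
    ggplot2,
    jsonlite,
    readr,
    stats,
    utils,
    generics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
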