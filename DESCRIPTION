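Package: grnavigate
Title: Curiosity-Driven Exploration and Robustness Analysis of Gene-Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the reachable goal states of ODE gene-network models with
    intrinsically motivated goal exploration (curiosity search), characterizes
    their robustness under trajectory-conditioned noise, push and wall
    perturbations, and reuses the same machinery for pseudopotential energy
    landscapes, stepwise setpoint-reset intervention design, and
    diversity-driven oscillator-circuit engineering. Models are supplied either
    as transcriptional gene circuits (weight matrix, bias, time constants) or
    through a generic rate-function contract integrated with deSolve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
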