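Package: indlinpk
Title: Inductive Linearization Solvers for Nonlinear Pharmacokinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Solves nonlinear pharmacokinetic ordinary differential
    equations by inductive linearization: the nonlinear system is
    iteratively replaced by a linear time-varying system built around the
    previous iterate's trajectory and integrated by piecewise
    eigendecomposition matrix exponentials. Includes a successive-error
    stopping rule, a slope-based adaptive step-size grid, ordinary
    least-squares parameter estimation by Levenberg-Marquardt with a
    smart-update warm start, and a stochastic simulation-estimation
    harness, demonstrated on a one-compartment Michaelis-Menten model
    with first-order absorption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
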