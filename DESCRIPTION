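Package: bdchoice
Title: Time-Dependent Solutions, Metastability and Calibration for
    Mean-Field Binary-Choice Birth-Death Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for finite-state birth-death master equations arising
    from mean-field binary decision dynamics (logit/Glauber, Arrhenius and
    Kirman recruitment rate families). Provides the exact transient
    distribution via the spectral resolvent method, the Kirchhoff
    steady state, exact stochastic simulation (Gillespie SSA), mean
    first-passage-time and metastability analysis including a two-state
    reduction of the relaxation rate, and composite-likelihood parameter
    calibration by differential evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
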