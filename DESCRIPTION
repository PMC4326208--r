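Package: ufhpk
Title: Population Pharmacokinetics of Unfractionated Heparin During
    Cardiopulmonary Bypass
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-compartment population pharmacokinetic modelling of
    unfractionated heparin (UFH) given as irregular intravenous boluses
    during cardiopulmonary bypass (CPB), with an instantaneous
    protamine-neutralization reset of the central compartment that
    reproduces post-operative heparin rebound.  Provides closed-form
    kinetics with dose superposition, a numerical ODE cross-check, a
    log-normal inter-individual variability and hybrid residual-error
    population layer with linear and conditional covariate effects, a
    synthetic CPB trial generator, first-order conditional estimation
    (FOCE) with stepwise covariate selection by objective-function value,
    bootstrap and visual predictive check validation, conditional
    weighted residual diagnostics, and simulation of post-operative
    protamine infusion regimens scored by rebound metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    deSolve,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    knitr
Config/testthat/edition: 3
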