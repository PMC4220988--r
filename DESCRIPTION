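Package: vpaggt
Title: Population PK-PD Modelling of Valproic Acid Exposure and Gamma-Glutamyltransferase Elevation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Nonlinear mixed-effects modelling of sparse steady-state valproic
    acid (VPA) concentrations with a one-compartment oral absorption model, and
    of the probability of serum gamma-glutamyltransferase (gamma-GT) elevation
    as a random-intercept logistic function of individual VPA exposure (AUC).
    Provides FOCE-with-interaction and Laplace marginal-likelihood estimation,
    forward-inclusion/backward-elimination covariate selection on objective
    function changes, stratified nonparametric bootstrap, visual predictive
    checks, goodness-of-fit diagnostics, Monte-Carlo prediction of gamma-GT
    elevation risk by dose, SOD2 Val16Ala genotype and intellectual disability,
    and a synthetic-cohort generator emulating the covariate structure of a
    Japanese epilepsy population, so the whole pipeline is testable without
    patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
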