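Package: copdjm
Title: Joint Modelling of FEV1 Progression, Bronchodilator Response and
    Informative Dropout in COPD Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and estimation tools for joint nonlinear
    mixed-effects modelling of trough FEV1 in chronic obstructive pulmonary
    disease (COPD) trials.  The longitudinal submodel is an indirect-response
    (turnover) model with linear disease progression and a
    kinetic-pharmacodynamic (KPD) Emax bronchodilator effect driven by dose
    alone; study discontinuation is modelled as a time-to-event process whose
    hazard depends on the model-predicted FEV1, making dropout informative.
    The package provides a virtual-trial generator with configurable
    covariate distributions, Laplace-approximated marginal-likelihood
    estimation of the joint model with optional prior penalties, stepwise
    covariate modelling, case-resampling bootstrap, and simulation-based
    diagnostics (dropout-aware visual predictive checks, Kaplan-Meier
    overlays, normalised prediction distribution errors).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    MASS,
    rlang,
    stats,
    survival,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
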