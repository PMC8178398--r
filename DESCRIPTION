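Package: slpfit
Title: Specific Loss Power Estimation from Non-Adiabatic Radiating Calorimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamic modelling of magnetic-nanoparticle hyperthermia
    calorimetry in a non-adiabatic, radiating regime. Computes the effective
    thermal conductance of a cylindrical sample holder surrounded by air from a
    conduction/convection resistance network, integrates the power-balance
    differential equation for the suspension temperature (magnetic heating
    against linear conductive/convective losses and Stefan-Boltzmann radiative
    losses) with a classic fixed-step fourth-order Runge-Kutta scheme, and
    estimates the specific loss power (SLP/SAR) and the effective thermal
    conductance from time-temperature traces with three estimators: the
    quasi-adiabatic initial-slope method, the Box-Lucas exponential-saturation
    fit, and a nonlinear least-squares fit of the radiating model itself.
    Includes a synthetic trace generator with known ground truth for validating
    the estimators by parameter recovery, cooling-phase corroboration of fits,
    and file-based workflows (CSV traces, YAML/JSON configuration, JSON fit
    results) with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
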