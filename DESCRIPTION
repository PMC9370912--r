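Package: ecgsim
Title: Model-Based Synthetic Electrocardiogram Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Synthesizes normal and pathological electrocardiogram (ECG)
    waveforms, including full 12-lead profiles, from four dynamical models of
    macroscopic heartbeat dynamics: a network of heterogeneous Van der Pol and
    FitzHugh-Nagumo oscillators for the cardiac conduction system, a spatially
    discretized reaction-diffusion (BVAM) system, a ring of three delay-coupled
    oscillators, and a quasi-periodic Gaussian-kernel state-space model. Models
    are integrated with a fixed-step fourth-order Runge-Kutta scheme with
    ring-buffer evaluation of time-delayed couplings. Ships a registry of rhythm
    presets (sinus rhythm, conduction blocks, tachycardias, flutter and
    fibrillation), Einthoven/Goldberger/Wilson lead algebra, R-peak based rate
    estimation, CSV and WFDB export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
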