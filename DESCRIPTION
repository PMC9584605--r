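Package: stpkit
Title: Kinetic Modelling and Train Analysis of Short-Term Synaptic Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and estimators for short-term plasticity at large
    glutamatergic synapses such as the calyx of Held. Implements a single-pool
    vesicle priming/fusion model with calcium-dependent replenishment and a
    sequential two-step (loose/tight docking) priming scheme; quantal analysis
    of EPSC trains by the Elmqvist-Quastel, back-extrapolation (SMN) and NpRf
    methods; bi-exponential recovery fitting with nested-model selection;
    miniature-EPSC detection and spike-timing (delay/jitter) analysis; a
    synthetic-data generator for every input; and an objective-based
    calibration stage with cross-condition parameter sharing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
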