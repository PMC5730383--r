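Package: follownet
Title: Spiking Recurrent Networks that Learn Forward Models via
    Error-Feedback Plasticity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates two-layer networks of heterogeneous leaky
    integrate-and-fire neurons that learn to emulate non-linear dynamical
    systems (linear and van der Pol oscillators, the chaotic Lorenz
    system, a two-link planar arm under gravity) with the FOLLOW scheme:
    readout decoders and fixed random error-feedback encoders form a
    negative-feedback auto-encoder loop around the recurrent population,
    and the feedforward and recurrent weights are trained online with a
    local plasticity rule driven by the filtered, fed-back output error.
    Provides population tuning-curve sampling, ridge-regression decoder
    solving, motor-babbling command generators, reference-system
    integrators, and scripted experiments for learning curves,
    realizable-reference weight recovery, readout relearning, robustness
    sweeps and Lorenz tent maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
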