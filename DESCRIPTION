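Package: growthswitch
Title: Growth-Feedback Dynamics of Bistable Self-Activation Gene Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deterministic multiscale modelling of a bistable self-activation
    gene circuit (AraC/pBad with a GFP reporter) carrying an auxiliary TetR
    repressive link, coupled to host growth through cellular burden and
    growth-dependent protein dilution. Provides the coupled ODE model,
    plate-reader-style experiment protocols (preconditioning, dilution into
    fresh media, timed observation), zero-growth fixed-point and separatrix
    analysis, dose-response and hysteresis construction, growth-rate collapse
    thresholds, pulse and drop-rescue metrics, synthetic plate-reader and
    flow-cytometry data generators, and least-squares parameter calibration
    with recovery diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    lhs,
    withr,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
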