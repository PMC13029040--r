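Package: mmtc
Title: Quantifying Mesozooplankton-Mediated Trophic Cascades in Plankton Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the indirect (cascade) effects of marine
    mesozooplankton on phytoplankton via their predation on microzooplankton.
    Provides Michaelis-Menten functional-response fitting and dilution-method
    grazing estimation, a three-level correction of bottle-incubation grazing
    rates (Frost log-ratio, microzooplankton background subtraction, and
    trophic-cascade compensation), the Cascade Strength index and a
    predator-prey size-matching efficiency kernel, temperature-response
    functions for warming scenarios, a mass-conserving four-compartment
    nutrient-phytoplankton-microzooplankton-mesozooplankton (NPMZ) ordinary
    differential equation model with sensitivity analysis, and a synthetic
    experiment generator with stored ground truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
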