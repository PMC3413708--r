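Package: pcskinetics
Title: Compartmental Kinetics of Cell-Cycle Arrest and Cellular Senescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation and least-squares fitting of a
    three-compartment model of primary fibroblast cultures, in which
    proliferating cells (P) enter a reversible cell-cycle arrest (C) and
    progress irreversibly to senescence (S). Transitions are driven by an
    external stress input (irradiation pulses, constant stress, or linearly
    accumulating replicative stress) filtered through a bistable cellular
    stress-response function. Includes population-doubling curve simulation
    with a population-extinction event, single-curve and joint multi-condition
    parameter estimation, fate-threshold classification, bifurcation and
    sensitivity analyses, senescence-marker comparison, and a seeded
    synthetic-data generator for growth curves and marker-positive fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
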