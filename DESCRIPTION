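Package: rtfsim
Title: Stochastic Mechanochemical Simulation of Regulated Thin Filament
    Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo simulation and analysis of calcium- and
    myosin-dependent activation of the regulated thin filament (actin
    decorated with troponin and tropomyosin). Implements a two-parameter
    regulation model (a calcium-dependent relative attachment rate and a
    fixed coupling distance over which strongly bound myosin locally
    activates the filament) on top of a four-state actomyosin crossbridge
    cycle with load-dependent ADP release. Simulates three experimental
    geometries: the three-bead laser-trap assay (single molecule and
    mini-ensemble), the in vitro motility assay, and an isometric
    half-sarcomere. Includes the trace-analysis event detectors used for
    laser-trap records (Page-type change-point, displacement threshold,
    variance drop), Hill and Michaelis-constant curve fitting with
    bootstrap uncertainty and chi-square goodness of fit, and synthetic
    data generators for all pipeline stages.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
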