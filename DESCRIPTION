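Package: countrysideSAR
Title: Countryside Species-Area Relationship Models for Extinction Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting short-term species extinctions under
    land-use change with species-area relationship (SAR) models. Implements
    the classic SAR, the countryside SAR (which weights human-modified
    habitat by a species-group affinity), and a linear plot-scale model,
    together with the algebra linking habitat affinities to plot-scale
    sensitivities. Includes a spatially explicit lattice landscape
    simulator with controlled native-habitat cover and fragmentation, a
    nested sampling-window analysis of how projected extinction fractions
    change with sampling grain, and utilities for summarising sensitivity
    databases of paired native/modified richness comparisons, including a
    three-way factorial ANOVA with eta-squared effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
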