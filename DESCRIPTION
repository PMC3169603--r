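Package: vpfields
Title: Simulation and Reference-Frame Analysis of Visual Performance Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the shape of visual performance fields
    (the horizontal-vertical anisotropy and vertical meridian asymmetry of
    discrimination accuracy at isoeccentric locations) and for deciding
    which spatial reference frame -- retinotopic, head-centric or
    allocentric -- a measured field is anchored to.  Provides the polar
    geometry of head roll and fixation displacement, a generative
    synthetic-observer model of 2AFC orientation discrimination, a grid
    implementation of the QUEST adaptive staircase, the arcsine-square-root
    accuracy transform with paired meridian contrasts and a fully
    within-subject 2x2x8 ANOVA, and a seeded bootstrap model-comparison
    engine that scores retinotopic against head-centric predictions of
    shifted-fixation performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
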