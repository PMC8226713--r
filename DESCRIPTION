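Package: thiolkin
Title: Kinetic and Neural-Network Modelling of Thiol-Group Decay in Stored Minced Meat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predictive modelling of protein oxidation, measured as thiol (SH)
    group loss, in stored minced meat. Implements zero-order degradation
    kinetics per storage temperature, Arrhenius temperature dependence fitted
    both by the classical two-stage linearization and by global
    Levenberg-Marquardt nonlinear least squares, a feed-forward neural-network
    (MLP) regression ensemble trained with BFGS, dummy-coded multiple linear
    regression for plant-extract treatment effects, external validation at a
    held-out storage temperature, and a seeded synthetic-data generator that
    emulates a full factorial storage-study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'ann.R'
    'arrhenius.R'
    'thiolkin-package.R'
    'dataset.R'
    'kinetics.R'
    'mlr.R'
    'pipeline.R'
    'synthetic.R'
    'validation.R'
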