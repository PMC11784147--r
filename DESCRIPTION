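Package: sandwichHSI
Title: SWIR Hyperspectral Prediction of Closed-Sandwich Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for predicting the composition of closed
    sandwiches (bread type, butter presence, filling type) from short-wave
    infrared hyperspectral images. Provides a hypercube data model with
    ENVI-style input/output and white/dark reference calibration, Standard
    Normal Variate scatter correction with spectral-derivative feature
    generation, a spatial partition-based subsampling scheme that guards
    against pixel interdependency between train and test sets, per-target
    classifiers (PLS-DA via SIMPLS, a classical roster selected by five-fold
    cross-validation, and a multi-layer perceptron with grid search and early
    stopping), confusion-matrix and log-loss evaluation, and a seeded
    synthetic sandwich-scene generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    nnet,
    ranger,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    knitr
Config/testthat/edition: 3
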