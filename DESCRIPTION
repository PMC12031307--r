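Package: bisfruit
Title: Bioimpedance Spectroscopy Modelling and Storage-Condition Classification for Fruit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bioelectrical impedance spectroscopy (BIS) of
    whole fruit. Provides a constant-phase-element equivalent-circuit forward
    model (modified Hayden topology with an electrode interface block), a
    bounded multi-start complex nonlinear least-squares fitter with a
    chi-square fit-quality gate, a seeded synthetic-cohort generator that
    emulates a two-size, two-storage-temperature mandarin study with
    storage-driven spectral drift, feature assembly for raw, time-delta and
    diameter-augmented datasets, and a repeated cross-validation benchmark of
    eight classifiers with paired Wilcoxon signed-rank comparison, compact
    significance letters and confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    e1071,
    glmnet,
    nnet,
    class,
    ranger,
    MASS,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
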