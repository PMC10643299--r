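Package: polcrab
Title: Polarization Imaging and Looming-Stimulus Behavioural Analysis for
    Crustacean Polarization Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for polarization-vision playback experiments with
    crustaceans: conversion of division-of-focal-plane polarization-camera
    mosaics into Stokes parameter, degree-of-polarization and
    angle-of-polarization maps with exposure masking and false-colour
    rendering; construction of expanding-disc looming stimuli parameterised
    in Weber (intensity) or degree-of-polarization contrast, including
    screen-calibration inversion and randomized presentation series; and
    behavioural analysis of trial tables via sigmoid contrast-response fits
    with half-maximum thresholds, habituation line fits, and mixed-effects
    binary logistic regression with likelihood-ratio tests. A synthetic-data
    module renders mosaics from known Stokes scenes and draws trial tables
    from a psychometric observer population with per-animal random effects,
    contrast-polarity asymmetry and per-trial habituation, providing ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    lme4,
    methods,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
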