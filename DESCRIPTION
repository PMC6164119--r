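Package: biosense
Title: Biosensory Session Analysis: Remote Photoplethysmography, Infrared
    Thermography and Multivariate Fusion of Sensory Panel Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for integrated biosensory sensory-evaluation sessions:
    builds and validates JSON session configuration files, reads and writes the
    tab-delimited response/ranking text dialect produced by tablet sensory
    forms, estimates heart rate (and, via a trainable regressor, blood
    pressure) from facial video using green-channel remote
    photoplethysmography, extracts maximum skin temperature from co-registered
    visible/thermal image pairs with eye-region detection and whole-face
    fallback, ingests facial-emotion tables (eight emotion intensities,
    valence, arousal, head pose, gaze), and fuses conscious and subconscious
    variables per sample for principal component analysis and
    Euclidean-distance hierarchical clustering. A seeded synthetic-data module
    generates face videos with injected pulse, visible/thermal pairs, session
    response files and emotion tables with ground truth, so the whole pipeline
    is testable without human-subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    MASS,
    pracma,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    withr
Config/testthat/edition: 3
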