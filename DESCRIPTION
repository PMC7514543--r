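Package: micwt
Title: Motor-Imagery EEG Decoding with Continuous Wavelet Transforms and a Shallow 1D-Kernel CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for decoding left- versus right-hand motor imagery from
    three-channel (C3, Cz, C4) EEG. Epochs are mapped to time-frequency
    images with a continuous wavelet transform (Morlet, Mexican hat, or Bump
    mother wavelet), the mu (8-13 Hz) and beta (13-30 Hz) band scalograms are
    combined into a fixed-size image, and a shallow convolutional network
    with full-height 1D kernels classifies the imagery side. Includes
    event-related desynchronization (ERD/ERS) quantification, a seeded
    synthetic EEG generator with a controllable lateralized ERD signature for
    offline testing, repeated k-fold cross-validation, and a self-describing
    text container format for all intermediate artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
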