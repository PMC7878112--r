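Package: covafuse
Title: Covariance-Contour Fusion of Multimodal Wearable Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Low-level sensor fusion for multichannel wearable recordings.
    A window of heterogeneous biosignals (accelerometry, photoplethysmography,
    electrodermal activity, temperature, heart rate, inertial measurements) is
    encoded as a single filled-contour image of its covariance matrix, either
    channel-by-channel (signal-wise) or sample-by-sample. The images feed an
    activity classifier: a small residual convolutional network trained from
    scratch, or a pluggable feature extractor with a linear one-vs-rest
    support-vector machine. Includes multi-rate signal ingestion (generic
    long-format CSV and the Empatica E4 export dialect), resampling and
    windowing, missing-completely-at-random degradation with moving-median
    imputation, k-fold and leave-one-subject-out cross-validation, a full
    battery of micro-averaged one-vs-rest confusion metrics, and a synthetic
    benchmark generator with analytically known covariance structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
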