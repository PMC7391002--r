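Package: prefeat
Title: Low-Level Visual Features, Item Categories, and Value-Based Preference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how low-level visual features (HSV colour
    statistics, Sobel-gradient sharpness, the spectral slope of the Fourier
    power spectrum) and category-specific features (market attributes of
    snacks, configural facial geometry) shape value-based preferences.
    Implements image feature extraction, a behavioural preprocessing cascade
    (participant-wise z-scoring, item/trial/participant exclusion), a
    Colley-matrix transitivity score for binary choices, mixed-effects models
    of preference ratings and binary choices, and a synthetic-data generator
    with stored ground truth for end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    grDevices
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
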