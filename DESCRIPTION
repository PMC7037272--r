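Package: otval
Title: Validation and Application of Targeted LC-MS/MS Quantification of
    Organotin Compounds in Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for the quantitative workflow of a targeted
    LC-MS/MS (MRM) method validation study and its application to
    environmental monitoring of organotin compounds (tributyltin,
    triphenyltin) in bottom sediments. Implements weighted 1/x calibration
    with back-calculation and signal-to-noise based quantification limits,
    EMA-style validation metrics (accuracy and precision, selectivity,
    carry-over, stability) with guideline acceptance logic, extraction
    recovery and absolute/relative matrix effects from pre/post-extraction
    spikes and slope ratios, trueness against a certified reference material
    with expanded uncertainty, exploratory statistics linking matrix effects
    to sediment geochemistry (Spearman screening, PCA biplots), censored
    reporting of real-sample concentrations, and a synthetic-data generator
    with known latent truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
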