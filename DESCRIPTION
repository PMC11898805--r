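Package: hsiq
Title: Hyperspectral Chemometrics for Sulfur-Fumigation Quality Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reproducible chemometrics pipeline for near-infrared
    hyperspectral screening of dried medicinal and food plants (lily bulb as
    the motivating crop): black/white reference reflectance calibration of
    ENVI cubes, region-of-interest mean spectra, VNIR/SWIR band fusion onto a
    396-band working grid, reference-assay arithmetic for polysaccharide,
    total-phenol and sulfur-dioxide contents, wavelength selection by
    interval random frog (iRF) and variable combination population analysis
    (VCPA) with a cross-validated partial-least-squares fitness, and four
    predictors (support vector machine and 1-D CNN, LSTM and CNN-LSTM
    networks) benchmarked over full and selected band sets for fumigation
    classification and content regression. Includes a seeded synthetic
    spectrum generator emulating the statistical structure such studies
    assume, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
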