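Package: cspws
Title: Simulation and Analysis of Chromatin-Sensitive Partial Wave
    Spectroscopic Microscopy for Colorectal Cancer Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for chromatin-sensitive partial wave spectroscopic
    (csPWS) microscopy studies of colorectal cancer field carcinogenesis.
    Provides a synthetic-data generator for spectral image cubes of cell
    nuclei with known chromatin packing scaling D (Gaussian random fields
    with power-law autocorrelation), a forward interference model and its
    calibrated inversion from spectral fluctuation statistics Sigma to
    per-pixel D maps, automated nucleus segmentation, patient-level cohort
    statistics (confounder screen, age regression, group comparisons with
    effect sizes, univariate split-sample ROC), a five-year cumulative
    colorectal-cancer risk model, and an AI classification pipeline
    (convolutional feature extraction, autoencoder compression, grid-searched
    random forest) evaluated by repeated stratified cross-validation with
    optimal-cutpoint sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    yaml,
    randomForest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Microscopy, Classification, Epigenetics
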