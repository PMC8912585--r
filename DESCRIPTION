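Package: phenoevi
Title: Satellite-Derived Phenology of Semi-Deciduous Mediterranean Shrublands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds, cleans and smooths Enhanced Vegetation Index (EVI)
    time series on the 8-day satellite composite calendar (BISE noise
    rejection, Fourier-harmonic smoothing with upper-envelope
    reweighting), extracts thirteen land-surface phenology metrics
    (spring leaf drop, summer dry period, autumn revival, annual
    extrema) with first-derivative and threshold rules, compares sites
    by paired tests, attributes phenological events and monthly EVI to
    lagged monthly climate windows through Pearson screening, stepwise
    multiple linear regression and random forests, fits interannual
    trends, and generates climate-coupled synthetic EVI and climate
    datasets with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
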