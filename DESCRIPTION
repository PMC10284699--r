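Package: watercarbon
Title: Interannual Coupling Between Tropical Water Availability and the
    Atmospheric CO2 Growth Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how the interannual relationship between
    tropical terrestrial water availability and the atmospheric CO2 growth
    rate (CGR) changes over time. Implements detrended annual-series
    preprocessing with volcano-year exclusion, bootstrapped (partial)
    correlations and ridge-regression climate sensitivities over fixed and
    moving windows, Nino-index based classification of Eastern-Pacific and
    Central-Pacific ENSO years, a spatial-coherence statistic for gridded
    water-storage anomalies with tercile-conditioned coupling analysis,
    model-ensemble diagnosis metrics with EOF decomposition, and a
    four-parameter arctangent calibration mapping vegetation optical depth
    to aboveground carbon. A synthetic-data generator emulates the
    statistical structure of the observational inputs so the full pipeline
    can be exercised and tested end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
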