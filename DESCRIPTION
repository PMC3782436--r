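Package: seasonsem
Title: Structural Equation Models Linking ENSO, Rainfall Seasonality and
    Wildfire Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes wet and dry seasons from daily rainfall records
    using cumulative rainfall anomalies (onset, cessation, duration, seasonal
    rainfall and the consistency of the drying or moistening trend), attaches
    season-weighted Nino 3.4 values, and analyzes the resulting descriptor
    tables with linear-Gaussian structural equation models: maximum-likelihood
    covariance fitting, chi-square goodness of fit, standardized path
    coefficients, direct/indirect/total effect decomposition, and exhaustive
    specification search ranked by the Browne-Cudeck criterion. Includes a
    catalog of reference path models for a subtropical Florida fire regime and
    synthetic-data generators (daily climate, ENSO index, annual wildfire
    records) with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
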