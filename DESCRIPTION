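Package: no2lur
Title: Satellite-Based Land-Use Regression Modelling of Annual NO2
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for developing and validating
    land-use regression (LUR) models of annual nitrogen dioxide from
    ground monitor series and gridded geographic predictors. Covers
    quality control and temporal aggregation of hourly monitor records,
    buffer-based predictor extraction at 22 radii, direction-constrained
    supervised forward variable selection, regression diagnostics
    (variance inflation, influence measures, Moran's I on residuals),
    repeated k-fold cross-validation, historical transfer evaluation
    with frozen coefficients, gridded prediction, and population-weighted
    aggregation to administrative units. Ships a seeded synthetic-world
    generator (spatially autocorrelated predictor fields, road networks,
    monitor networks with known ground truth) so every stage is testable
    end to end without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    car,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
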