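Package: lursim
Title: Land-Use Regression Exposure Modelling with Synthetic Geography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates land-use regression (LUR) models for
    small-scale spatial variation in outdoor NO2, together with a
    CAR-style screening dispersion comparator. Provides a synthetic
    geography generator (road networks with traffic flows, categorical
    land-use and population rasters, monitoring campaigns with
    facade/curbside placement protocols and sampler loss), GIS predictor
    extraction (circular-buffer traffic and land-use variables, log
    distance and flow at the nearest road by road class), inverse
    distance weighted regional background estimation, multiple
    imputation of missing period concentrations by chained equations
    with pooling by Rubin's rules, supervised forward selection with
    sign constraints and backward pruning, leave-one-out and
    cross-campaign validation, and an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
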