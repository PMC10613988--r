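Package: uavyield
Title: UAV Multispectral and RGB Imagery Pipeline for Plot-Scale Wheat
    Yield Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts multi-temporal spectral features (band reflectances,
    vegetation and color indices), gray-level co-occurrence texture
    features, and agronomic trait parameters (canopy height from
    DSM-DEM differencing, fractional vegetation cover from supervised
    crop/soil classification, canopy volume) from plot-scale UAV
    imagery, and predicts grain yield with random-forest regression
    under single-feature, exhaustive feature-combination, per-growth-
    stage, and cross-cultivar evaluation protocols.  A synthetic scene
    generator emulates a two-cultivar by four-nitrogen-rate field
    trial with seven flight dates so the whole pipeline is testable
    without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
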