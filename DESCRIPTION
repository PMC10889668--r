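Package: hydrogb
Title: Granular-Ball Rough Set Feature Selection for Water-Quality Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for predicting algal chlorophyll biomass from tabular
    hydrological and water-quality monitoring data. Implements granular-ball
    rough set (GBRS) attribute reduction driven by positive-region coverage,
    a Pearson-correlation ranked-removal feature sweep, a k-nearest-neighbour
    regressor and a back-propagation network, the standard regression error
    metrics (RMSE, MAE, MAPE, R-squared), leakage-free cross-validated
    pipelines comparing the selection strategies, and a synthetic
    monitoring-table generator with planted informative, redundant and noise
    attributes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
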