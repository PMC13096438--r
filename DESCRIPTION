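Package: topwet
Title: TOPMODEL-Based Wetland Extent Diagnosis, Calibration and Scenario Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnoses basin wetland extent from column soil moisture with a
    TOPMODEL-style topographic-index threshold, calibrates the per-basin
    transmissivity-decay parameter M against multi-period observed wetland
    areas by RMSE grid search, projects wetland area under multi-model
    climate-scenario ensembles with grid-cell agreement maps, and provides
    the accompanying change-accounting, trend-testing and map-accuracy
    statistics. Includes a seeded synthetic-data generator emulating basin
    topographic-index distributions, climate-model soil-moisture cubes,
    observed wetland areas and labelled validation points, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
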