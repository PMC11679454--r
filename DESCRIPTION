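Package: poachrisk
Title: Poaching-Risk Inference from GPS-Collar Telemetry via Knowledge
    Graphs and Geo-Location Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for wildlife-conservation informatics:
    simulates or ingests GPS-collar observation tables, maps them into an
    ontology-based RDF knowledge graph (Forest Observatory Ontology plus the
    W3C WGS84 geo vocabulary), extracts observation rows by SPARQL-style
    pattern matching, forecasts future animal geo-locations with a sequential
    neural network benchmarked against linear, polynomial and vector
    autoregression baselines, re-inserts the predictions into the graph, and
    asserts a binary poaching indicator by a great-circle (haversine) buffer
    rule around hazard sites such as oil-palm plantations.  Includes Turtle
    serialization, GeoJSON buffer export, chronological and expanding-window
    time-series cross-validation, and RMSE evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
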