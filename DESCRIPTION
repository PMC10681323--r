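Package: reeftrace
Title: Residency, Site-Fidelity and Movement-Network Analysis of Passive
    Acoustic Telemetry Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing passive acoustic telemetry detections of
    reef-associated sharks (and other tagged marine animals): receiver-calendar
    resolution and false-detection filtering, per-individual residency indices
    and a rule-based residency classification, detection- and site-fidelity
    indices with receiver ranking, minimum linear displacement from
    great-circle distances, station utilization and monthly activity indices,
    directed movement networks with Mantel overlap and node-degree
    comparisons, a nonparametric statistical toolkit, and an agent-based
    simulator of detection logs with known ground truth for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    lubridate,
    ggplot2,
    generics,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    geosphere,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
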