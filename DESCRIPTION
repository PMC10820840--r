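Package: chitopt
Title: Response-Surface Modelling and Pareto Optimization of Chitosan Deacetylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing the alkaline deacetylation of chitin to
    chitosan. Builds rotatable central composite designs in coded factors
    (NaOH concentration, liquid:solid ratio, duration), converts raw
    characterization measurements into the response variables (potentiometric
    deacetylation degree, viscometric molar mass via the
    Mark-Houwink-Sakurada equation, extraction yield), fits and reduces
    second-order response-surface models by ordinary least squares, and
    optimizes the fitted surfaces: analytic stationary-point maximization,
    a deterministic grid Pareto oracle, and an NSGA-II genetic algorithm for
    the bi-objective trade-offs between deacetylation degree and molar mass.
    Ships a 17-run shrimp-waste deacetylation experiment as a packaged
    dataset together with a synthetic-data generator for end-to-end testing.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LazyData: false
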