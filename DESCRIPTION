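Package: pasm
Title: Price-Endogenous Agricultural Sector Modelling for Peri-Urban
    Pesticide Policy Analysis
Version: 0.1.0
Authors@R:
    person("PASM", "Developers", email = "pasm@example.org", role = c("aut", "cre"))
Description: Builds and solves a price-endogenous partial-equilibrium model of
    a peri-urban agricultural region: welfare-maximizing allocation of crop
    acreage across districts and technologies under land limits, crop-mix
    convexity restrictions, and pesticide-use quantity caps imposed at
    district or regional scale. Includes calibration of linear inverse demand
    from observed price/quantity/elasticity points, survey-derived technology
    budgets with equivalent-annual-cost machinery annualization, a
    scenario-grid runner (reduction level x technology x imposition scale x
    market closure), Fisher/Laspeyres/Paasche indexes, validation-ratio
    tables, and a synthetic-data generator so every stage is testable
    offline. A dense primal-dual interior-point solver for convex quadratic
    programs is built in; shadow prices (land rents, pesticide permit
    values) are extracted from the dual solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
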