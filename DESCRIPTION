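Package: agroplan
Title: Farm-Level Precision Land Management by Mixed-Integer Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Pre-season planning of seed selection and irrigation frequency
    for a spatially heterogeneous farm. A square grid of land units, each
    carrying one soil class, is tiled into rectangular decision units; a
    mixed-integer linear program then assigns one management option (seed
    hybrid x irrigation frequency) per decision unit so as to maximize
    annual net farm profit under irrigation, operating, yield, and seasonal
    water constraints. Includes an exact branch-and-bound solver with a
    brute-force verification oracle, a seeded generator of realistic
    synthetic farms, management-scale scenario tables, relative-gain
    analysis for constrained irrigation patterns, one-at-a-time sensitivity
    and break-even analysis, and a log-scale regression of profit against
    management granularity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
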