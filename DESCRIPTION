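Package: caribouscen
Title: Scenario-Based Disturbance, Habitat, and Demographic Projection for Boreal Caribou
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scenario-based cumulative-effects assessment of boreal
    woodland caribou (Rangifer tarandus caribou) ranges. Computes buffered
    anthropogenic and wildfire disturbance footprints as percentages of a
    range, projects seasonal resource selection function (RSF) surfaces from
    published coefficient tables and diagnoses their cross-range
    transferability, and links disturbance to demography through beta
    regressions for adult female survival and recruitment, with stochastic
    population projection (interannual variation, demographic stochasticity,
    density dependence) over land-use scenarios. Includes a seeded synthetic
    landscape and scenario generator so the full workflow runs with no
    external data, plus a command-line interface for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
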