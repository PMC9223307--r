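Package: esdbalance
Title: Ecosystem-Service Supply, Demand and Balance Assessment from Land Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for regional ecosystem-service
    supply-demand assessment from categorical land-use grids. Supply is
    valued by the equivalent-factor method (per-class, per-service value
    coefficients times area); demand is a composite index of land-use
    degree, population density and a nighttime-light composite index;
    their per-zone difference is a balance index classified by Jenks
    natural breaks into surplus/balance/deficit typologies; and the
    association between balance and land-use composition is estimated by
    check-loss quantile regression with bootstrap standard errors. A
    seeded synthetic-landscape generator (Markov land-use transitions,
    class-dependent population and night-light fields, contiguous zones)
    makes every stage testable without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
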