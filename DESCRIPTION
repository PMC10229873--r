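Package: phycoculture
Title: Dynamic Modelling and Response-Surface Optimization of Microalgal
    Photobioreactor Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling batch cultures of photosynthetic microalgae
    in bubble-column photobioreactors. Implements a multi-substrate Monod
    growth model with biomass light shading, gas-liquid mass transfer of
    carbon dioxide and oxygen, and a linear pH surrogate; sum-of-squares
    parameter estimation against culture time series with multistart
    derivative-free search; two-factor (carbon dioxide by light intensity)
    factorial response-surface regression with ANOVA-based term pruning and
    Derringer-Suich desirability optimization; elemental-balance checking of
    photosynthesis stoichiometry; and a synthetic-data generator for
    replicate-level factorial tables and noisy culture trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
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
    withr,
    knitr
Config/testthat/edition: 3
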