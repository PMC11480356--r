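Package: ddgrowth
Title: Density-Dependent Somatic Growth in Age-Structured Fish Stocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify density-dependent (DD) somatic growth
    in age-structured fish stock assessments. Reads long-format stock panels
    (numbers-, weight-, maturity-, mortality-at-age), prunes constant-weight
    periods, computes unfished equilibrium reference points (SSB0, R0, SPR0 and
    numbers-at-age) by deterministic closed form and by stochastic projection
    with a hockey-stick stock-recruitment relationship, builds instantaneous
    (W_recr, W_old, W_std versus relative recruitment or de-circularised
    relative spawning biomass) and intracohort (standardised weight-increment)
    response panels, and fits linear mixed models with per-stock density
    slopes, stock random effects and AR1 within-group residual correlation by
    maximum likelihood, with delta-AIC model selection and per-stock slope
    inference. A synthetic multi-stock generator with known injected DD
    effects supports end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
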