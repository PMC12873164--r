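Package: wheatclim
Title: Agro-Climatic Analysis of Warming Impacts on Rainfed Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how multi-decadal warming reshapes the
    phenology and yield of rainfed winter (rabi) wheat. Provides a stochastic
    daily weather generator (linear warming trend, harmonic seasonality,
    AR(1) temperature noise, Markov-chain/gamma rainfall), phase-aware
    growing-degree-day accumulation with cardinal temperatures and a
    ceiling-zero heat-stress rule, sowing-date scenario tables with
    flowering-window temperature statistics, stage-partitioned rainfall
    summaries, a surrogate yield model for temperature and CO2 sensitivity
    grids, crop-model evaluation metrics (R2, RMSE, MAE, bias, 1:1
    regression), polynomial trend regression and descriptive statistics, and
    a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    withr,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
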