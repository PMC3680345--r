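Package: censuscast
Title: Ensemble Forecasting of Hospital Unit Census Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Short-term forecasting of daily census counts in hospital units
    (such as a neonatal intensive care unit) that combines a
    seasonality-adjusted Poisson autoregressive model for daily arrivals with
    stratified, time-varying-covariate logistic models for patient departure
    probabilities. Point forecasts and percentile prediction intervals are
    obtained from a stochastic ensemble that propagates both parameter
    uncertainty and arrival/departure randomness, and models are evaluated with
    a continuously-updating (expanding-window) backtest. Includes a synthetic
    patient-flow generator with a covariate-dependent discrete-time departure
    hazard for fully reproducible experiments.
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
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
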