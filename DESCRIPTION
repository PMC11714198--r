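Package: greenhits
Title: Probabilistic Multi-Step Forecasting of Greenhouse Soil Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Short-term multivariate point and interval forecasting of greenhouse
    soil temperature from environmental sensor series. Implements gradient-boosted
    feature ranking with backward elimination, an N-HiTS forecaster (multi-rate max
    pooling, residual backcast stacking, hierarchical interpolation) with a
    Gaussian-likelihood probabilistic head and Monte-Carlo prediction intervals,
    interval quality metrics (PICP, PINAW, PINRW, CWC), baseline interval
    constructors (error fitting, bootstrap, quantile loss), and speed-constrained
    multi-objective particle swarm optimization of hyperparameters over joint point
    and interval objectives. Includes a synthetic greenhouse series generator with
    analytic forecast-distribution oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
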