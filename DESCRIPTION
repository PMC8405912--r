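Package: molfarmUQ
Title: Uncertainty Quantification for Techno-Economic Models of Field-Grown
    Plant-Based Manufacturing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo uncertainty quantification for techno-economic models
    of ultra-large-scale field-grown plant molecular farming. Provides a
    temperature-driven tobacco dry-weight growth model with an RMSE-minimising
    fitter, conversion of hourly weather into monthly yield predictions and a
    four-parameter (scaled) beta yield-input distribution, a registry of
    assumption distributions with rank-correlation induction, a transparent
    surrogate batch-process and economics model (IRR after tax, cost of goods
    sold, annual throughput, product purity) with effective-value clamping
    under fixed equipment sizing, a reproducible trial loop, post-simulation
    analyses (scenario comparison tests, normality assessment, tornado and
    spider sensitivity, contribution to variance, extremal trials), and
    grid-search optimization of the cation exchange column diameter under
    uncertainty using common random numbers. Synthetic-data generators supply
    hourly weather and growth-chamber fixtures so the full pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
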