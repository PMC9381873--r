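Package: pharmacast
Title: Weekly Pharmacy-Chain Drug Sales Forecasting with Shortage and
    Outlier Handling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Short-horizon forecasting of weekly drug sales for a retail
    pharmacy chain. Provides eight exponential-smoothing-family
    forecasters (naive, moving average, single exponential smoothing,
    Brown-style double smoothing, Holt's linear trend, and three
    Holt-Winters variants), mean imputation of stockout (shortage)
    weeks, Grubbs-test outlier detection with three-sigma winsorization,
    four hierarchical planning approaches (chain-level versus
    per-pharmacy forecasting, each with or without outlier response),
    and accuracy-based method selection via MAPE, MSE and a Theil-type
    U2 ratio against the naive benchmark. Includes a seeded synthetic
    panel generator for pharmacy chains with injected shortages and
    panic-buying spikes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
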