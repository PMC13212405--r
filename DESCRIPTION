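Package: cogapfill
Title: Gap Imputation and Residual-Bias Certification for Hourly CO
    Monitoring Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputes medium-length (25-72 hour) gaps in hourly carbon
    monoxide monitoring series using gradient-boosted trees with lagged
    features and two recurrent neural networks (LSTM and simple RNN)
    driven by 48-hour sliding windows, all applied in a recursive
    multi-step scheme. Provides an artificial-gap benchmark builder that
    respects the placement constraints of real station data, per-gap
    accuracy metrics with distributional comparison, and a residual-bias
    certification procedure that routes each gap by a Ljung-Box test to
    either a one-sample t test or a conservative combination of a
    Newey-West HAC test and a moving-block bootstrap. A seeded synthetic
    station generator with traffic-driven diurnal seasonality and
    MAR-style gaps makes every stage testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
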