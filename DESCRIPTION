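Package: cgmforecast
Title: Blood Glucose Forecasting from Continuous Glucose Monitoring Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for short-term blood glucose forecasting from
    single-channel continuous glucose monitoring (CGM) traces sampled every
    five minutes. Provides gap-length-routed hybrid imputation of missing CGM
    data (cubic-spline interpolation for short gaps, ARIMA forecasting with
    outlier purging for medium gaps, series cutting for long gaps), derived
    glucose features with glycemic-state labelling, a small recurrent neural
    network forecaster predicting glucose 30 minutes ahead, clinical
    evaluation via regression metrics, multiclass Matthews correlation and
    Clarke Error Grid analysis, and a seeded synthetic CGM simulator for
    end-to-end testing without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
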