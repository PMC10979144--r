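Package: pmhia
Title: Health Impact Assessment and Seasonal Modelling of Ambient PM2.5
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the long-term health burden of fine
    particulate matter (PM2.5). Cleans hourly monitoring series, aggregates
    them to 24-hour means and binned exposure distributions, evaluates
    concentration-response functions (log-linear relative risk per 10 ug/m3
    increment and the integrated exposure-response form), and chains them
    into attributable proportion, attributable rate per 100,000 and excess
    cases with low/central/high uncertainty bounds. Also fits a seasonal
    ordinary-least-squares model of daily PM2.5 on monthly indicators, a
    linear trend and meteorological covariates, and ships a synthetic
    hourly-data generator with known coefficients for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
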