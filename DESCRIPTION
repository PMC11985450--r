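Package: apcprev
Title: Forecasting Cancer Incidence and Prevalence with Age-Period-Cohort
    and Survivorship Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the log-linear age-period-cohort (APC) model for cancer
    incidence rates through its estimable functions (net drift, longitudinal
    and cross-sectional age curves, cohort and period rate-ratio curves),
    projects rates forward and backward in time by joinpoint-style
    piecewise-linear extrapolation of the rate-ratio curves, models all-cause
    survival after diagnosis with an additive discrete-time log-hazard spline
    in time since diagnosis, age at diagnosis, and period of diagnosis, and
    estimates cancer prevalence as the convolution of lagged incidence with
    modeled survival.  Includes model averaging across forecast forms,
    counterfactual trend scaling, parametric-bootstrap uncertainty for
    prevalence, population burden and survivorship counts, and synthetic-data
    generators with an individual-level microsimulation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
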