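Package: icudyn
Title: Dynamic Mortality Prediction from ICU Vital-Sign Time Series in
    Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic 30-day mortality prediction in intensive-care
    patients with traumatic brain injury monitored for intracranial pressure.
    Implements 5-minute-median preprocessing of intracranial pressure (ICP),
    mean arterial pressure (MAP) and Glasgow Coma Scale time series with
    physiologic artifact filtering and cerebral perfusion pressure (CPP)
    derivation; cohort inclusion and death-censoring rules; rolling-window
    dynamic feature engineering (begin/end/trend aspects of windowed means,
    differences, variances, percentiles and threshold exceedance fractions);
    recursive feature elimination and weakly penalized logistic risk modelling
    with a rolling 8-hour prediction schedule; time-dependent discrimination
    via repeated stratified patient-grouped cross-validation; a static
    IMPACT-style admission-covariate comparison model with binned calibration;
    and a synthetic ICU cohort generator so the full pipeline is testable
    without patient data.
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
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
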