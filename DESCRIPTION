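Package: actimpute
Title: Ensemble-Averaging Imputation for Wearable Posture Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for long-term posture monitoring with trunk-worn
    tri-axial accelerometers. Classifies each one-minute epoch of a
    recording day into reclining, sitting-or-standing, or walking from
    the trunk declination angle and a rules-based step detector, then
    imputes data losses by ensemble averaging across measurement days:
    at each time of day the fraction of valid days spent in each posture
    is converted into a fractional posture period, so an epoch is missing
    only when every measurement day lost data at that same time of day.
    Includes a conventional best-day-selection baseline, missing-rate
    metrics, a block-loss injection harness for validating imputation
    stability, a synthetic inpatient-session generator, 24-hour activity
    visualisations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    grid,
    rlang,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
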