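Package: torportel
Title: Rest-Phase Torpor Responses from Skin-Temperature Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying rest-phase torpor responses of
    small birds to a daytime predation-risk manipulation, from raw
    temperature-sensitive transmitter pulse intervals to linear mixed-model
    effect estimates. Fits per-transmitter cubic calibration curves, segments
    telemetry records into circadian rest and active phases, estimates
    individual normothermic baselines and torpor thresholds, computes nightly
    torpor depth and duration, and models treatment and weather effects with
    random-intercept and random-slope mixed models. Includes a synthetic
    telemetry generator with known planted parameters so the whole pipeline is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    lme4,
    lmerTest,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    optparse,
    knitr
Config/testthat/edition: 3
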