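Package: walkcap
Title: Six-Minute Walk Test Standardization and Case-Control Capacity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardizes six-minute walk test (6MWT) measurements against
    North African reference equations (predicted distance, lower limit of
    normal, fitness age, maximal predicted heart rate), derives per-participant
    capacity metrics (percent-predicted distance, walk work, rest-to-end delta
    changes, physiological cost index), classifies exercise-intolerance signs
    (abnormal distance, desaturation, chronotropic insufficiency), and runs the
    full case-control statistical comparison (nonparametric tests, odds ratios,
    Hedges' unbiased effect size, mean percentage change, two-sample
    sample-size planning). Includes a seeded synthetic-cohort generator with a
    calibration preset emulating a chronic hepatitis B case-control study, so
    the whole pipeline is testable without access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
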