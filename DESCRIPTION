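Package: moodphone
Title: Predicting Negative Emotions from Mobile Phone Usage Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for personalized prediction of three
    negative emotions (depression, anxiety, stress) from passively logged
    mobile phone usage. Infers discrete usage events (calls, app sessions,
    screen time) from raw polled call-state and foreground-app samples,
    extracts windowed usage statistics around visual-analog-scale emotion
    reports, selects per-user features by two-level t-test filters and
    greedy wrapper searches, compares four classifier families across
    candidate timeslots by rank-product scoring, and evaluates the chosen
    personalized detector prospectively on a fixed daily prediction
    schedule. Ships a synthetic cohort generator with planted, tunable
    usage-to-emotion dependence so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    jsonlite,
    e1071,
    rpart,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
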