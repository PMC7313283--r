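Package: wearwell
Title: Composite Physical Well-Being Scoring from Wearable Device Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a composite physical well-being indicator from
    consumer wearable-device time series. Daily measurements (steps,
    activity time by intensity, sleep phases, heart-rate summaries) are
    aggregated into weekly or monthly summaries, scored into four
    rule-based domain indices (walking activity, physical activity,
    sleep duration, cardio-respiratory fitness via non-exercise VO2max
    estimation), and composed into a weighted geometric-mean indicator.
    Includes scoring for 15-item well-being (ESS-style) and five-dimension
    health-status (EQ-5D-like) questionnaires, correlation-based
    validation of the composite against questionnaire scores, and a
    seeded synthetic cohort generator for end-to-end testing.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
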