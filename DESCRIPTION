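Package: trescore
Title: Objective and Subjective Adherence Scoring for Time-Restricted Eating Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring adherence to time-restricted eating (TRE)
    protocols in free-living intervention studies. Detects eating-driven
    glucose excursions in continuous glucose monitoring (CGM) traces,
    computes eating windows from time-stamped diet diaries, scores each
    24 h period against protocol criteria (window reduction, target
    eating times, CGM/diary agreement), aggregates adherence by study
    phase, and summarises exit-questionnaire responses. Includes a
    synthetic cohort generator with known ground truth so every stage of
    the pipeline can be validated without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
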