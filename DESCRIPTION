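Package: perisim
Title: Simulation of Variability and Reliability Critical Times in Longitudinal Visual Field Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo simulation of longitudinal visual field (perimetry)
    series summarized by mean deviation. Cohorts are sampled with
    subject-specific baseline mean deviation, progression rate, intrinsic
    test-retest variability and intrinsic reliability; testing schedules with
    one to four tests per visit over a range of review intervals are derived
    from a common core series. Rolling-window criteria estimate the critical
    time at which running estimates of variability and reliability stabilize,
    either relative to each other or relative to the ground truth, with
    censoring at the schedule horizon. Includes cohort summaries (medians,
    cumulative detection curves, group tests, difference-from-truth analyses,
    baseline-predictor regressions) and a closed-form signal-to-noise
    calculator for the probability of detecting a fixed mean-deviation
    difference given variability and tests per visit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
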