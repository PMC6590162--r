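Package: metatau
Title: Confidence Intervals for the Between-Study Variance in Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Q-profile and generalized Q-statistic (GENQ) confidence
    intervals for the between-study variance (tau-squared) in
    random-effects meta-analysis, together with the Paule-Mandel point
    estimator. Includes a binomial 2x2-table data generator for log odds
    ratio meta-analyses with the conventional +0.5 continuity correction,
    enumeration-based exact moments of the corrected log odds ratio, and a
    Monte-Carlo harness for studying coverage probabilities, interval
    widths and the sampling distribution of the generalized Q-statistic
    when the normality and known-variance assumptions of the
    random-effects model are violated (rare events, small samples).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
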