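Package: intrudr
Title: Distractor-Intrusion Rates as a Measure of Individual Differences
    in the Speed of Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing distractor-intrusion (DI) rates in rapid
    serial visual presentation (RSVP) tasks as an individual-differences
    measure of attention speed. Provides trial scoring and exclusion rules
    for DI, attentional-blink, time-judgment and speeded reaction-time
    tasks; split-half and Cronbach's alpha reliability with Spearman-Brown
    correction and an iterative down-sampling reliability grid; a circular
    time-judgment error pipeline; frequentist and Bayesian association
    statistics (including Bayes factors for correlations under a stretched
    beta prior and JZS t-test Bayes factors); sample-size planners for
    group comparisons and correlations; and a calibrated latent-trait
    synthetic cohort generator for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
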