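Package: glucowear
Title: Analysis of Wearable Glucose-Program Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 28-day digital metabolic-health programs that
    combine continuous glucose monitoring (CGM), heart-rate tracking, and
    self-logged meals, activity and body weight. Provides a synthetic cohort
    generator with a known injected behavior-change effect, inclusion and
    quality-control filters for wearable streams, CGM outcome metrics (time in
    range, glucose management indicator, excursion event rates, glycemic
    variability) with baseline-versus-end subgroup comparisons,
    logging-bias-adjusted diet and activity metrics, a probabilistic recurrent
    (LSTM) next-step glucose predictor with post-meal forecasting, virtual-CGM
    rollout and ablation-based feature importance, and a nutrient-similarity
    food recommendation engine with personalised intervention targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
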