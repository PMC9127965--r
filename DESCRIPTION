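Package: egload
Title: Estimated Glycemic Load Modelling and Validation for Processed Foods
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for glycemic index (GI) and glycemic load (GL) analysis of
    postprandial blood-glucose curves, and for fitting and externally
    validating a nutrient-label prediction model of glycemic load (eGL).
    Computes incremental area under the glucose curve (IAUC) with
    baseline-cut geometry, per-subject GI against a glucose-solution
    reference, GL per serving, and an estimated GL from labelled
    carbohydrate, fibre, protein and fat. Ships transcriptions of a
    24-food validation table and cohort summaries so the full pipeline
    runs without external data, plus validation machinery:
    transportability comparisons from summary statistics, logistic
    calibration with the Hosmer-Lemeshow test, ROC/AUROC discrimination
    with Hanley-McNeil confidence intervals, and correlation/regression
    agreement, overall and by subgroup. A synthetic-cohort simulator
    reproduces the study design (fasting baseline, seven fixed sampling
    times, eight subjects per food) for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
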