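Package: pqsofa
Title: Age-Adjusted Modified qSOFA Scoring and Prognostic Evaluation for
    Pediatric Sepsis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the age-adjusted modified quick Sequential Organ
    Failure Assessment (qSOFA) score for children, built from capillary
    refill time, respiratory rate, heart rate and AVPU responsiveness with
    age-banded 95th-centile vital-sign thresholds, and evaluates its
    prognostic value for 28-day all-cause mortality in the paediatric
    intensive care unit.  Provides tie-corrected Mann-Whitney ROC/AUC
    estimation from raw values or grouped score counts, DeLong standard
    errors, confidence intervals and paired AUC comparisons, Youden-index
    cutoff selection with confusion-matrix summaries, a combined logistic
    model adding serum lactate and blood glucose, Hosmer-Lemeshow
    calibration testing, and a synthetic-cohort generator that reproduces
    the grouped statistical structure of a derivation and a temporal
    validation cohort so the whole pipeline can be exercised without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
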