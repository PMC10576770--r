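Package: painindex
Title: Baseline-Adjusted Machine-Learning Pain Index from ICU Vital Signs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous visualization of pain in critically ill
    patients from per-minute vital signs. Establishes per-patient vital-sign
    baselines with a stability-detection algorithm (coverage, Friedman rank
    test and coefficient-of-variation gates over the first stable
    post-admission hour), computes deviation-from-baseline features over the
    hour preceding each Critical-Care Pain Observation Tool (CPOT)
    assessment, trains a class-balanced random forest (adaptive synthetic
    oversampling inside cross-validation folds) whose predicted probability
    of CPOT >= 3 is the pain index, and evaluates analgesic treatment
    response around fentanyl boluses. Includes a synthetic ICU cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
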