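Package: biradsvar
Title: Observer Variability in BI-RADS Ultrasound Features and Bayes
    Computer-Aided Diagnosis of Breast Masses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of intra-observer variability in
    categorical BI-RADS ultrasound feature coding and its effect on a
    naive-Bayes computer-aided diagnosis of solid breast masses. Generates
    synthetic cohorts with class-conditional feature tables and per-class
    age distributions, produces repeated noisy observations with
    controllable per-feature agreement (target Cohen's kappa), computes
    per-feature and pooled kappa with Landis-Koch labels, fits the Bayes
    probability-of-malignancy model with leave-one-out cross-validation
    (with or without an age term), and compares diagnostic performance
    across observations via the empirical ROC area with DeLong standard
    errors, paired DeLong tests, and two-way absolute-agreement intraclass
    correlation of the probability estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    withr
Config/testthat/edition: 3
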