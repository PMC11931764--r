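Package: darndest
Title: Layered Contrast-Sparing MRI Triage for Detecting Local Recurrent
    Nasopharyngeal Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating a two-level triage strategy (DARNDEST) that
    layers a contrast-enhanced MRI model over an unenhanced-MRI model for the
    follow-up detection of local recurrent nasopharyngeal carcinoma. Provides
    score fusion, Youden-index and sensitivity-floor cutoff selection, triage
    of patients into positive, suspicious and negative management groups,
    diagnostic-performance statistics (sensitivity, specificity, accuracy,
    PPV, NPV with Wald confidence intervals, McNemar's Z test, ROC/AUC with
    DeLong paired comparison), a hypothetical-cohort cost and examination-time
    model, and a calibrated synthetic score-cohort generator for testing the
    full pipeline without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), pROC, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
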