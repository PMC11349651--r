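Package: capscore
Title: Clinical Beta-Amyloid Positivity Prediction Score (CAPS)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the Clinical beta-Amyloid Positivity Prediction Score
    (CAPS), an additive 0-4 point clinical score that predicts cerebral
    beta-amyloid positivity in people with clinical Alzheimer syndrome from
    three routinely collected observations: neuropsychiatric symptom burden
    (NPI-Q), rapid cognitive decline on serial MMSE, and white matter
    microangiopathy (Fazekas rating). Includes the CAPS-MT extension with a
    medial temporal atrophy (Scheltens) component, clinical-scale utilities
    (MoCA to MMSE conversion, NPI-Q aggregation, Hachinski and CSF biomarker
    classification), annualized-decline computation, cohort statistics
    (normality-gated two-group comparisons, binary logistic regression,
    ROC/AUC with DeLong confidence intervals, confusion-matrix operating
    characteristics), a calibrated synthetic memory-clinic cohort generator,
    and a reproducible end-to-end scoring pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    nortest,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
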