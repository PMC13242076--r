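Package: toxconcord
Title: Concordance Between Clinician-Graded Toxicities and Patient-Reported Symptom Severity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying agreement between clinician-graded adverse
    events (CTCAE, grades 0-4) and patient-reported symptom severity from the
    EORTC QLQ-C30/BR23 questionnaires in two-arm oncology trials. Implements
    EORTC symptom-scale scoring (half-rule, 0-100 linear transformation, four-level
    severity categorization), harmonization of the two instruments onto a common
    ordinal scale, weighted (quadratic) and unweighted Cohen's kappa with
    asymptotic null tests, classification of matched pairs as agreement,
    clinician underreporting, or overestimation, exact binomial predominance
    tests, McNemar paired-change tests, two-sample proportion tests, and a
    synthetic two-arm trial generator with known ground truth for validating
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
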