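Package: aaqcat
Title: Graded Response Model Adaptive Testing for the Animated Activity
    Questionnaire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A graded response model (GRM) engine for computerized adaptive
    testing (CAT) of polytomous patient-reported outcome items, bundled with
    the published 17-item parameter bank of the Animated Activity
    Questionnaire (AAQ), a measure of activity limitations in hip and knee
    osteoarthritis. Provides marginal-maximum-likelihood (EM) calibration of
    item banks, expected-a-posteriori (EAP) scoring with posterior standard
    errors, maximum-Fisher-information item selection with standard-error and
    test-length stopping rules, post-hoc and generative CAT simulation, and a
    psychometric validation battery: Mokken scalability and monotonicity,
    Q3-style residual correlations for local independence, Orlando-Thissen
    S-X2 item fit via the generalized Lord-Wingersky recursion, ordinal
    logistic regression DIF screening, and a modal-category diagnostic for
    disordered thresholds. A study harness simulates synthetic cohorts and
    compares CAT versions on test length, precision, RMSE, bias and score
    agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
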