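Package: ctgtier
Title: Rule-Based Intrapartum Cardiotocography Classification and
    Diagnostic Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Executable rule engines for four intrapartum cardiotocography
    (CTG) classification systems (FIGO 2015, RCOG 2001, NICHD 2008 and the
    Parer-Ikeda five-tier colour system) over fetal-heart-rate features
    extracted from paired FHR/tocodynamometry signal windows: baseline
    estimation, minute-scale variability, acceleration and deceleration
    detection with typing (early/variable/late/prolonged) and severity
    grading, and sinusoidal-pattern detection. Includes a diagnostic
    evaluation toolkit for ordered-category classifiers (per-category
    sensitivity, specificity, likelihood ratios and predictive values,
    tie-corrected Mann-Whitney ordinal AUC with analytic and bootstrap
    confidence intervals, Fleiss kappa), a seeded synthetic CTG generator
    with ground-truth feature bundles, and packaged case-control category
    counts from a published comparison of the four systems for predicting
    severe neonatal acidemia (umbilical artery pH < 7.00).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
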