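Package: adipodiscrim
Title: Discriminant Screening of Adipokine and Metabolic Markers in
    Insulin-Treated Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for paired before/after
    clinical biomarker studies of obese type 2 diabetics under long-acting
    insulin therapy.  Provides a Gaussian-copula cohort generator
    calibrated from published per-group marginal moments and pairwise
    correlations, the per-patient difference transform with its
    correlation screen and Student's t comparisons, five two-class
    Gaussian discriminant classifiers (linear, diaglinear, quadratic,
    diagquadratic, Mahalanobis), and an exhaustive feature-subset search
    scored by held-out classification accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
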