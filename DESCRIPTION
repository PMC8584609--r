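Package: crpkin
Title: Postoperative C-Reactive Protein Kinetics and Early Periprosthetic
    Joint Infection Prediction after Primary Hip Arthroplasty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the postoperative C-reactive protein (CRP) course after
    primary hip arthroplasty and predicts early acute periprosthetic joint
    infection (PJI). Provides peak and second-peak detection in longitudinal
    CRP series, peak-aligned normalization and one-phase exponential decay
    fitting, a failure-to-decline rule with an additive 15-percentage-point
    margin, published linear risk scores (single CRP-maximum cut-off, binary
    and multinomial logistic scores), ROC analysis, per-day group comparisons
    with the two-stage Benjamini-Krieger-Yekutieli false-discovery-rate
    procedure, a-priori sample-size calculation for point-biserial
    correlations, and a seeded synthetic-cohort generator emulating the
    statistical structure of routine postoperative CRP surveillance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    stats,
    tibble
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
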