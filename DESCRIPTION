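Package: thyrosens
Title: Central Sensitivity to Thyroid Hormones and Urinary Iodine in Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantile-based assessment of central sensitivity to thyroid
    hormones in pregnancy cohorts. Computes the Thyroid Feedback
    Quantile-based Index (TFQI) per measurement from the joint distribution
    of free thyroxine and thyrotropin, removes urinary-iodine outliers with
    Tukey's inter-quartile-range fence, classifies iodine nutritional status
    against the 100/150/250 microgram-per-litre thresholds, and runs the
    period-wise inferential toolkit (stratified Pearson correlation with a
    pairs bootstrap, one- and two-way ANOVA with Tukey-Kramer post hoc
    testing, chi-square tests, per-stratum OLS fits). A Gaussian-copula
    synthetic cohort generator with moment-matched lognormal marginals
    emulates the structure of trimester-wise thyroid-panel data so the full
    pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
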