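Package: ttevax
Title: Sequential Target-Trial Emulation of Vaccination Effects on
    Anxiety and Depression Symptoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Emulates a sequence of nonrandomized trials from
    longitudinal survey data to estimate the intention-to-treat analog
    of the effect of COVID-19 vaccination (at least one dose) on
    moderate-to-severe anxiety (GAD-7 >= 10) and depression (PHQ-8 >= 10)
    symptoms, stratified by vaccine-availability era. Provides GAD-7 and
    PHQ-8 scoring, a synthetic longitudinal cohort generator with
    covariate-driven vaccine uptake and missing-at-random outcomes,
    person-trial construction with person-specific time zero, multiple
    imputation of missing outcome scores with Rubin's-rules pooling,
    era-stratified pooled logistic regression with cluster-robust
    (sandwich) variance, subgroup and random-intercept linear mixed
    model analyses, a Wald test of effect heterogeneity across eras,
    and publication-style descriptive tables and flow summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    lme4,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
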