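Package: ordagree
Title: Rank-Invariant Agreement and Disagreement Analysis for Paired
    Ordinal Data
Version: 0.1.0
Authors@R:
    person("Ordagree", "Maintainers", email = "maintainers@ordagree.org",
           role = c("aut", "cre"))
Description: Analysis of paired assessments on ordered categorical rating
    scales, as used to validate patient-reported outcome questionnaires
    and to compare raters.  Observed disagreement is decomposed into a
    systematic, group-level component (Relative Position, RP) and an
    additional individual-level component (Relative rank Variance, RV,
    built on augmented mean ranks, and the disorder measure D), alongside
    percentage agreement, Spearman rank correlation and ordinal
    median/quartile summaries.  Confidence intervals are obtained by
    subject-level percentile bootstrap or jackknife resampling.  A
    latent-trait generator simulates paired ordinal studies with
    per-source bias, noise, observer heterogeneity and missingness, and a
    pipeline reads study data from CSV, analyses every item and writes
    publication-style report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
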