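Package: openfieldr
Title: Behavioral Analysis of Virtual Open-Field-Test Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying anxiety-related movement behavior in the
    (virtual) open field test from time-stamped 2D position logs. Computes
    the classical behavioral indices (time in the outer region, region-wise
    path length and walking speed, mean proximity to the wall, and
    line-crossing counts on a 7x7 bin raster: thigmotaxis, center entries,
    center ambulation, center leaves), simulates random teleporting agents
    with wall rejection to obtain expected values for these indices, and
    provides the inferential layer used to compare observed cohorts against
    those expectations: one-sample and paired t-tests with noncentral-t
    confidence intervals for Cohen's d, Pearson correlations with Bonferroni
    correction, a correlation-sign chi-squared test, and one-way
    repeated-measures ANOVA with Greenhouse-Geisser correction and partial
    eta-squared with noncentral-F confidence intervals. A synthetic-cohort
    generator with a tunable wall-attraction bias and trait-questionnaire
    scores makes every pipeline stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
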