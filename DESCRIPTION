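Package: ipdlmm
Title: One-Stage Individual Participant Data Meta-Analysis of Continuous
    Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits one-stage individual participant data (IPD) meta-analysis
    linear mixed models for continuous outcomes, with stratified or random
    trial intercepts, common or random treatment effects, maximum likelihood
    (ML) or restricted maximum likelihood (REML) estimation, and standard
    normal, Kenward-Roger, or Satterthwaite confidence intervals for the
    summary treatment effect.  Also provides a seeded Monte-Carlo simulation
    framework (data-generating mechanisms over a grid of meta-analysis
    scenarios, a replication engine, and performance summaries: bias,
    empirical standard error, mean squared error, coverage, convergence) for
    evaluating these estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
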