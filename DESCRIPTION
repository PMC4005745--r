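Package: secchitrend
Title: Hierarchical Bayesian Trend Analysis of Citizen-Collected Lake Water
    Clarity Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for long-term trend analysis of citizen-collected Secchi
    depth (water clarity) monitoring records. Provides QA/QC filtering and
    lake-year aggregation of raw Secchi observations, a synthetic cohort
    generator with known ground truth for validation, a Metropolis-within-Gibbs
    sampler for a hierarchical model with lake-specific intercepts, slopes and
    residual variances (optionally regressed on lake-level covariates such as
    latitude, surface area and median sample date), Gelman-Rubin convergence
    diagnostics, and posterior summaries: population trend as percent change
    per year, per-lake trend probabilities and classifications, covariate
    importance calls and inter-annual variability statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda
Config/testthat/edition: 3
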