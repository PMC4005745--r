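# secchitrend

Long-term trend analysis of citizen-collected lake water clarity records.

Volunteer monitoring programs in the Upper Midwest (USA) have measured lake
water clarity as **Secchi depth** — the depth (m) at which a standard disk
lowered into the water disappears — for decades, some records reaching back
to 1938. `secchitrend` turns such raw, messy observation tables into
population- and lake-level clarity trends: it provides the QA/QC and
aggregation pipeline, a hierarchical Bayesian trend model fitted by a
Metropolis-within-Gibbs sampler written for this model, posterior summaries
(percent change per year, per-lake trend probabilities, covariate
importance), and a synthetic-cohort generator with known ground truth so the
whole pipeline is verifiable by simulation.

## The model

Let `y_ij = log mean summer Secchi depth` of lake *j* in year *i*, and
`x_ij` the calendar year centered at the record's mean. The unconditional
model is

```
y_ij        ~ Normal(beta0_j + beta1_j * x_ij, sigma_j^2)
(beta0_j,
 beta1_j)   ~ BivariateNormal((mu_beta0, mu_beta1),
                              SDs (sd_beta0, sd_beta1), correlation rho)
log sigma_j ~ Normal(mu_logsigma, sd_logsigma^2)
```

so every lake has its own intercept, trend slope, and inter-annual residual
variance, all partially pooled. Priors are non-informative: Normal(0, 1e6)
on locations, Uniform[0, 100] on SDs, Uniform[-1, 1] on `rho`. The
covariate model regresses the three lake-level means on one standardized
lake attribute `z` (latitude, log10 surface area, or median sample date):
intercept `g00 + g01 z`, slope `g10 + g11 z`, log residual SD `h0 + h1 z`;
a coefficient is called important when its 95% credible interval excludes
zero. A log-scale slope `b` converts to a trend of `100*(exp(b) - 1)`
percent per year.

Sampling is Metropolis-within-Gibbs: conjugate bivariate-normal updates for
the lake lines and the population means, and reflected random-walk
Metropolis for the SDs, the correlation, and the lake log residual SDs,
with proposal scales adapted during burn-in only. Default chain protocol:
3 chains, 10,000 burn-in, every 3rd draw retained until 20,000 draws total.
Convergence is checked with the Gelman–Rubin scale reduction factor.

## Worked example

Simulate a 150-lake cohort with known truth (population trend 0.92 %/yr)
and realistic contamination, run it through QA/QC, fit the model, and
report:

```r
library(secchitrend)

design <- cohort_design(n_lakes = 150, seed = 20,
                        contamination = c(feet = 0.03, outlier = 0.01,
                                          offseason = 0.02))
bundle <- make_recovery_bundle(design)

run <- pipeline_from_table(bundle$observations)
qaqc_summary(run$obs)
#> $n_rows [1] 20779      $retained [1] 20164
#> $depth_ceiling_removed [1] 208   $out_of_season_removed [1] 407
#> $unit_converted [1] 638          $ingest_rejects [1] 0

md  <- build_model_data(run$lake_years)
fit <- fit_unconditional(md, settings = mcmc_settings(3, 800, 2, 1800, seed = 20))
render_report(run$lake_years, fit, path = "report")
```

The plain-text report reads:

```
Secchi depth trend analysis
===========================
Population trend: 0.97 %/yr (95% CRI 0.73 to 1.19)
Lakes: 150 | increase 70 (46.7%), decline 3 (2.0%), no trend 77
Covariate section: absent (no covariate fits supplied)
Inter-annual CV: 75% of 147 lakes below 30%
```

The estimated population trend (0.97 %/yr, CRI 0.73–1.19) brackets the
generating truth of 0.92 %/yr; the 638 feet-recorded rows, 208 injected
>30 m outliers and 407 out-of-season rows are exactly the rows converted or
removed by QA/QC; and most lakes have inter-annual CVs below 30%. Scale
reduction factors for all population parameters are within 1.02 of 1
(`gelman_rubin_all(fit)`). File-based workflows start from
`read_observations()` instead of `pipeline_from_table()`; covariate fits
use `derive_lake_covariates()`, `standardize_covariates()` and
`fit_with_covariate()`.

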