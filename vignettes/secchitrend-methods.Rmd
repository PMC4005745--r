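---
title: "Methods: hierarchical trend analysis of citizen Secchi records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical trend analysis of citizen Secchi records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secchitrend)
```

## The problem

Citizen volunteers have measured lake water clarity as Secchi depth for
decades across thousands of lakes, but the raw records are heterogeneous:
readings logged in feet, transcription outliers, observations scattered
across seasons, and monitoring windows that range from a single summer to
three decades anywhere within 1938–2012. `secchitrend` implements a
complete, testable path from such raw tables to defensible long-term trend
statements, with every stage validated against synthetic cohorts whose
ground truth is known.

## QA/QC and aggregation

The cleaning rules are deliberately few and auditable:

* depths recorded in feet are converted with the exact factor 0.3048 m/ft;
* readings strictly deeper than 30 m are removed as transcription errors
  ("exceeded 30 m" is read strictly, so a reading of exactly 30 m is kept);
* only June–August readings are kept (months 6–8, both boundary days
  inclusive), removing inter-seasonal variation;
* the modeling response is the **arithmetic mean of the retained raw
  (untransformed) depths per lake and summer** — the log transform happens
  at model-building time, not at aggregation time.

Every filter *flags* rows rather than deleting them, so
`retained + removed = input` holds for each step, filters are idempotent,
and `qaqc_summary()` accounts for every row. Unparseable input lines are
counted and reported with reasons at ingest; nothing is dropped silently.
Duplicate (lake, date) readings are all retained and enter the summer mean,
since no deduplication rule is part of the cleaning contract.

Lake covariates are derived from the cleaned record: latitude, surface
area, and the **median sample date** — the median of the calendar years
possessing a lake-year record (a lake monitored 1980–2000 has median date
1990); with an even number of record years the midpoint of the two central
years is used. Record years rather than raw observation dates are used
because the modeled response is annual. Surface area is log10-transformed
by default (areas span orders of magnitude; a raw-scale option exists).
All covariates are standardized (mean 0, SD 1 over the modeled lakes) with
the (center, scale) pairs stored so the transform inverts exactly.

## The hierarchical model

With `y_ij` the log lake-year mean and `x_ij` the centered year:

* `y_ij ~ N(beta0_j + beta1_j x_ij, sigma_j^2)` — each lake has its own
  line and its own inter-annual residual variance;
* `(beta0_j, beta1_j)` bivariate normal with means `(mu_beta0, mu_beta1)`,
  SDs `(sd_beta0, sd_beta1)` and correlation `rho`;
* `log sigma_j ~ N(mu_logsigma, sd_logsigma^2)` — residual SDs are
  lognormal across lakes, so inter-annual variability itself is modeled.

Priors are non-informative: N(0, 1e6) for locations, Uniform[0, 100] for
SDs (placed on SDs, not variances), Uniform[−1, 1] for `rho`.

The **year covariate is centered, not z-scored**. Centering keeps the slope
in per-year units so `100*(exp(mu_beta1) − 1)` is directly the population
trend in percent per year, and makes the intercept the expected log clarity
at the record's mean year. A z-scored year would silently rescale the slope
and break the percent-per-year reading. `build_model_data()` records the
centering constant and accepts an explicit one, which simulation studies
use to align fitted intercepts with generating intercepts.

The covariate model replaces the three lake-level means by linear functions
of one standardized lake attribute `z`: intercept `g00 + g01 z`, slope
`g10 + g11 z`, log residual SD `h0 + h1 z`. The second-stage intercept and
slope deviations keep their bivariate correlation, and the log-sigma
equation keeps an independent residual SD — the deviations from the
covariate lines are modeled exactly as richly as in the unconditional
model. One covariate is fitted at a time (latitude, log10 area, median
sample date as three separate fits), so coefficient triples are comparable
across fits. Importance is an interval statement: a 95% credible interval
(empirical 2.5–97.5 percentiles, linear-interpolation quantile rule) that
excludes zero strictly; an interval touching zero counts as overlap.

## The sampler

The uniform priors on SDs and on `rho` break full conjugacy, so the fitter
is a Metropolis-within-Gibbs scheme:

* **conjugate** bivariate-normal draws for each lake's `(beta0_j, beta1_j)`
  (vectorized across lakes via closed-form 2×2 algebra), for the population
  means (2-dimensional, or 4-dimensional for the `g` coefficients of the
  covariate model), and for `mu_logsigma` / `(h0, h1)`;
* **random-walk Metropolis** for each `log sigma_j` (lake-parallel,
  conditionally independent acceptances), and for `sd_beta0`, `sd_beta1`,
  `rho`, `sd_logsigma`, with proposals **reflected** at the prior bounds
  (reflection keeps the proposal symmetric, so no Jacobian correction is
  needed and bounded supports are respected by construction);
* proposal scales adapt toward a ~44% acceptance rate **during burn-in
  only** and are frozen afterwards, so the retained chain is a valid,
  fixed-kernel Markov chain;
* chains start from per-lake least-squares estimates jittered by
  chain-indexed amounts (over-dispersed, deterministic from the seed);
  all densities are computed on the log scale.

Default protocol: 3 chains, 10,000 burn-in iterations, every 3rd draw
retained until 20,000 draws are kept in total (pooled across chains —
"total" is read as pooled, configurable otherwise). Convergence is
assessed by the Gelman–Rubin scale reduction factor
`sqrt(((n−1)/n W + B/n)/W)` per parameter.

Determinism: a fit is bit-reproducible from `(data, settings, seed)`, and
`build_model_data()` sorts lake-years canonically so row order of the
input cannot change results. Relabeling lakes permutes the lake-level
columns but maps the RNG stream differently, so relabeling equivariance
holds in distribution, not draw-for-draw.

## The synthetic cohort generator

The generator emulates the structure of a multi-decade volunteer database:
a configurable number of lakes; record lengths uniform on [1, 34] years,
each window placed uniformly inside 1938–2012; 3–12 readings per summer
(about 7 on average, matching roughly 149,000 observations per 21,000
lake-years in large compiled databases); latitudes in the 41–49°N band;
lognormal surface areas. Lake parameters are drawn from exactly the
hierarchical law the model assumes, with defaults chosen once as plausible
regional values: mean log clarity `log 2.4`, mean slope 0.0092 (0.92 %/yr),
`sd_beta0 = 0.5`, `sd_beta1 = 0.01`, `rho = −0.2`, `mu_logsigma = log 0.2`
(typical inter-annual CV near 20%, so most lakes fall under a 30% CV),
`sd_logsigma = 0.5`.

Two variance knobs are separated deliberately. The model's `sigma_j` is the
**inter-annual** residual SD of annual mean log clarity around the lake's
trend line, so the generator draws one deviation per lake-year with SD
`sigma_j`. Individual readings within a summer then scatter around their
annual mean with a small **within-summer** SD (default 0.05 log units).
Because the pipeline averages raw depths before taking logs, within-summer
noise adds a small bias (~`tau^2/2` in log units) and extra variance
(~`tau^2/n`) to the response; at the defaults both are negligible relative
to `sigma_j`, and the noiseless limit (both knobs zero) reproduces the true
annual means exactly — which is tested.

Contamination for QA/QC exercises is injected mutually exclusively per row
with ground-truth labels: feet-recorded rows (value divided by 0.3048, unit
set to "ft", so conversion restores the physical depth), >30 m transcription
outliers (uniform 31–45 m), and out-of-season dates (May or September).
Clean readings are capped at the 30 m plausibility ceiling so the injected
outliers are *exactly* the rows the ceiling filter removes; this makes
QA/QC recall checkable row-for-row and mirrors the assumption that genuine
regional readings do not exceed 30 m. One seed drives all stages (each
stage derives its stream from it with a fixed offset), so bundles
regenerate bit-for-bit, and persistence (CSV tables at 17 significant
digits plus a JSON manifest) round-trips losslessly.

What the generator does **not** emulate: spatial autocorrelation among
lakes, state-program reporting quirks beyond the three contamination types,
and right-skewed record-length distributions (the default is uniform;
the distribution is configurable). Passing recovery tests therefore shows
the pipeline and sampler are correct *under the assumed generative law*,
not that real citizen data satisfy that law.

## Validation strategy and problem sizes

Correctness is established against independent oracles rather than against
another MCMC engine:

* **closed form** — with the residual SD and all population parameters
  pinned, a lake's line has a known normal posterior; sampler moments must
  match within 3 Monte-Carlo SEs;
* **grid quadrature** — on a 2-lake instance with known variance
  components, lake lines are marginalized analytically and the population
  means integrated on a dense grid; sampler marginal means must match
  within 0.02. A 1-D grid over `rho` validates the reflected Metropolis
  update specifically;
* **simulation-based recovery** — cohorts of 300 lakes: in each of 20
  replicates the seven hyperparameter CRIs must cover truth at least 16
  times each; cohorts generated with a strong intercept effect
  (`g01 = 0.25` on standardized latitude) and a null slope effect
  (`g11 = 0`) must yield an excluding and a covering CRI, respectively, in
  at least 18 of 20 replicates;
* **exact checks** — QA/QC removals equal injected contamination counts
  exactly; the scale reduction factor reproduces a hand-computed value
  (`sqrt(4.5)` for chains {1,2} and {3,4}) and sits in [0.99, 1.05] on
  i.i.d. chains, and agrees with an independent implementation.

Validation fits use reduced chain lengths (3 chains, 800 burn-in, thinning
2, 1800 retained draws at 300 lakes) — the package's chosen sizes for
routine verification; scale reduction factors at these sizes are within a
few percent of 1, and the full default protocol remains available for
production analyses.

## Numerical choices and edge cases

* Quantile rule for CRIs: linear interpolation (type 7), documented because
  interval endpoints depend on it.
* Trend classification: inclusive thresholds (`p >= 0.90` is an increase,
  `1 − p >= 0.90` a decline); slope draws exactly zero count as not
  positive; classifications are monotone in the threshold.
* Lakes with a single year are retained in fits; their slopes are informed
  entirely by pooling. Lakes need two years for an inter-annual CV.
* Zero-SD covariates refuse to standardize; constant covariates refuse to
  fit; a single chain refuses a scale reduction factor, as do chains with
  zero within-chain variance.
* `sd_beta1` can approach zero under near-degenerate data; the conjugate
  lake-line update guards its 2×2 Cholesky with a non-negativity clamp on
  the trailing pivot, and reflected proposals keep all scales inside their
  prior support without rejection loops.

## Known limitations

The sampler is written for this model family, not as a general PPL: one
covariate per fit, no spatial random effects, no model-comparison criteria.
Posterior draws of extreme lake-specific quantities (e.g., very short
records) inherit the usual hierarchical shrinkage and should be read as
partially pooled estimates, not per-lake maximum-likelihood fits. The
percent-per-year reading of the population slope relies on the centered
(not z-scored) year covariate; if a z-scored year is configured, slopes
must be rescaled before interpretation.
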