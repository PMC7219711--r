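---
title: "Methods: hierarchical estimation of the income elasticity of obesity prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical estimation of the income elasticity of obesity prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`obelast` studies the relationship between national income and adult
obesity prevalence with a two-stage hierarchical random-coefficients model.
The first stage is a country-specific time-series regression; the headline
specification is log-log,

$$\ln(\mathrm{prev}_{ct}) = \alpha_c + \beta_c \ln(\mathrm{GDPPC}_{ct}) + \varepsilon_{ct},
\qquad \varepsilon_{ct} \sim N(0, \sigma_c^2),$$

so that $\beta_c$ is the income elasticity of obesity prevalence: the
percent change in prevalence per 1% change in GDP per capita. The second
stage pools the country coefficients across countries and lets
standardized macro-environmental moderators $x_c$ shift them:

$$(\alpha_c, \beta_c) = (x_c'\theta_\alpha,\; x_c'\theta_\beta) + \pi_c,
\qquad \pi_c \sim \mathrm{MVN}(0, \Sigma).$$

Moderators are organized into five dimensions — globalization orientation,
demographic characteristics, economic environment, labor market
characteristics, and strength of health policies — and non-dummy moderators
are z-scored so the elements of $\theta_\beta$ are comparable effect sizes.
Male, female and overall prevalence are fitted as three separate models of
this form rather than jointly; the package filters by the `stratum` column.

A per-country homoskedastic error variance $\sigma_c^2$ is used. A
variance specific to each country-year is not identifiable from a single
observation per cell, so within-country homoskedasticity is the weakest
identifiable assumption consistent with country-specific noise levels.

## Estimation: conjugate Gibbs sampler

Both stages are estimated jointly. With conjugate priors every full
conditional is available in closed form and the sampler cycles four blocks:

1. **Country coefficients** $(\alpha_c, \beta_c)$: multivariate normal,
   combining the country's least-squares information
   $W_c'W_c/\sigma_c^2$ with the second-stage prediction $\Delta'x_c$ and
   covariance $\Sigma$. This is the classical precision-weighted shrinkage
   of noisy country slopes toward the moderator plane.
2. **Error variances** $\sigma_c^2$: scale-inverse-chi-square with
   $\nu_0 + T_c$ degrees of freedom.
3. **Second-stage coefficients** $\Delta = [\theta_\alpha\; \theta_\beta]$:
   matrix-normal around the ridge-stabilized multivariate regression of the
   stacked country coefficients on $X$.
4. **Coefficient covariance** $\Sigma$: inverse-Wishart.

The blocks are implemented in RcppArmadillo and draw exclusively from R's
own RNG, so a single `set.seed()` at sampler entry makes retained draws
bit-reproducible; diagnostics consume no random numbers and cannot perturb
a run. Each block is also exported individually, which lets the test suite
check every conditional's empirical mean and covariance against its closed
form (within three Monte-Carlo standard errors) on a small problem — a much
sharper correctness check than end-to-end summaries alone.

### Priors and their defaults

| parameter | default | meaning |
|---|---|---|
| `A` | 0.01 | precision of the flat normal prior on $\Delta$ (prior sd 10 per coefficient) |
| `nu`, `V` | 5, `5*I` | inverse-Wishart prior on $\Sigma$, the weakest proper choice at `dim + 3` |
| `nu0`, `s02` | 3, 0.01 | scale-inverse-chi-square prior on $\sigma_c^2$ |

The error-variance scale deserves comment. National prevalence series are
very tight on the log scale (residual sd of a few percent), so the prior
sum of squares $\nu_0 s_0^2$ must be small or it dominates every country's
residual information: with `s02 = 1` the posterior for $\sigma_c^2$ would
sit near $3/T_c$ regardless of the data, inflating country-level
uncertainty about thirtyfold, slowing mixing, and destroying the property
that a noiseless panel concentrates the posterior on the generating
coefficients. The default `s02 = 0.01` (prior residual sd 0.1) is still a
weak prior — two pseudo-observations' worth against 40 years of data — but
on the right scale. All priors are configurable through `prior_config()`.

### Run length and burn-in

The defaults are 50,000 iterations with the first 30,000 discarded and
every 10th subsequent draw retained (2,000 retained draws). Burn-in is
counted in raw iterations and thinning applied afterwards; other readings
of "burn-in plus thinning" change only the retained count, and both knobs
are exposed in `mcmc_config()`. The recovery simulations in the test suite
use 5,000 iterations with burn-in 2,500 and thinning 5, which this
sampler's mixing (effective sample size near the retained count on
synthetic panels) makes ample.

## Functional-form contest

Three candidate first-stage forms — linear, quadratic in GDPPC, and
log-log — are fitted per country by OLS and compared by mean absolute
percentage error. Two choices matter:

- **Common scale.** A log-scale model cannot be MAPE-compared against
  percent-scale models coherently unless all fitted values are placed on
  the same scale, so log-log fits are back-transformed with `exp` before
  the MAPE. No smearing correction is applied; with log-scale residual sd
  around 0.05 the retransformation bias is about 0.1% of the level, far
  below the differences the contest adjudicates. This is a documented
  limitation rather than an oversight.
- **Per-country OLS, in-sample.** The contest needs only relative fit, and
  hierarchical shrinkage affects all three forms similarly, so the full
  sampler is reserved for the winning form. Note that in-sample MAPE
  mildly favors the quadratic (three parameters per country against two);
  the contest is therefore validated in the tests on noiseless data, where
  the generating form always wins exactly, and on noisy log-log data,
  where log-log beats linear in at least 95% of replicates.

GDPPC is rescaled to thousands before the quadratic fit; the squared
column is otherwise so ill-conditioned that coefficients lose most of
their precision.

## Moderator forward selection

Selection operates in fast two-step mode: the response is the vector of
per-country OLS elasticities and candidate models are ordinary
least-squares regressions scored by AIC and BIC, with the full Gibbs model
re-estimated once on the final set. Candidates whose absolute pairwise
correlation with an already-selected variable exceeds 0.7 (configurable)
are inadmissible.

- **Phase 1** adds one variable at a time until each of the five
  dimensions is represented, at each step taking the best-BIC candidate
  with a coefficient significant at the 5% level (best-BIC with a warning
  if none is significant; when AIC and BIC disagree, BIC wins on parsimony
  grounds).
- **Phase 2** continues over all remaining admissible candidates and stops
  when no addition improves BIC by at least 2 — the conventional
  "positive evidence" margin for BIC differences. A zero margin would
  admit any candidate with $t^2 > \ln n$ (about a 3% false-continue rate
  per candidate at $n = 147$), which with a handful of leftover noise
  candidates would terminate cleanly in far fewer than nine of ten null
  runs; the margin of 2 brings the per-candidate false-continue rate to
  about 1%.

The criterion is computed on the elasticity equation, since moderation of
the elasticity is the scientific target; the intercept equation is refit
with the same selected set. Selection is fully deterministic given its
inputs.

## Geweke convergence diagnostic

For each second-stage coefficient chain the diagnostic compares the mean
of the first 10% of draws with the mean of the last 50%, standardized by
spectral-density-at-zero estimates of each segment mean's variance
(Bartlett lag window, window length $\lceil 4 (n/100)^{1/4} \rceil$).
$|Z| < 1.96$ is the pass criterion. On i.i.d. chains of length 2,000 the
observed pass rate is around 94–95%, and the test suite cross-checks the
scores against an independent implementation that uses an AR-fit spectral
estimator instead of a lag window (agreement is loose by construction —
the estimators differ — but signs always match and scores track closely).
The pipeline treats a failed chain as a soft failure: it warns and
continues, since a borderline score among twenty-odd chains is expected at
the 5% level even at convergence.

## Forecasting and sensitivity scenarios

Forecasts compound prevalence along each country's projected income-growth
path: for elasticity draw $b$ and year $y$,

$$\mathrm{prev}_{y+1} = \mathrm{prev}_y \left(1 + s_y \beta_b \frac{g_y}{100}\right),$$

where $g_y$ is annual income growth in percent and $s_y$ a scenario
multiplier. Bridge years between the panel's end and the projection
horizon use actual growth with $s_y = 1$. One thousand elasticity draws
per country are taken from the retained posterior by deterministic
thinning (seeded resampling with replacement if fewer are retained).
Aggregation across countries is an unweighted mean within each draw,
consistent with the package's descriptive conventions; the reported
average annual growth is the mean (with a 2.5/97.5-percentile prediction
interval) of per-draw CAGRs over the horizon, with the CAGR of the mean
trajectory also reported since the two differ by a Jensen gap — the
documentation deliberately does not claim they coincide.

The five standard scenarios estimate elasticities from the full window,
the most recent 15 years, and the most recent 10 years, plus two policy
scenarios in which the recent-10-year elasticities decline for a total
drop of 10% or 20% by the final horizon year. The decline is a linear
ramp — reading a "decline over the forecast period" as gradual — reaching
exactly $1 - d$ in the final year; a step mode is available. Yearly
compounding is used throughout rather than a single total-period
adjustment. Trajectories are clamped to $[0, 100]$ with an event counter;
on default synthetic configurations no clamping occurs.

## The synthetic data generator

The generator emulates the structure the estimator assumes: a 147-country,
40-year panel (years labelled 1975–2014 for familiarity) with log-log
first stage, second-stage coefficients driven by ten moderators (two per
dimension, the health-policy pair as Bernoulli dummies, continuous
moderators exchangeably correlated at 0.2), GDP per capita starting from a
log-normal spread (log-mean 8, log-sd 1.5) and following geometric growth
with country drifts $N(0.02, 0.01^2)$ and annual shocks $N(0, 0.02^2)$,
and observation noise of 0.05 on the log-prevalence scale. The true mean
elasticity is 1.2, with moderator effects on the elasticity of
$(+0.05, -0.06, -0.05, +0.01)$ on the first four moderators and
$\Sigma = \mathrm{diag}(0.3^2, 0.15^2)$.

Two calibration choices deserve explanation:

- **Baseline prevalence level.** With incomes spanning three orders of
  magnitude across countries and a unit-plus elasticity, the term
  $\beta_c \ln(\mathrm{GDPPC})$ varies by several log units across
  countries, so a common intercept consistent with the $(0, 100)$ support
  forces a low baseline prevalence (default $\theta_\alpha$ intercept
  $-13$). Every estimand in the package — elasticities, moderation
  effects, MAPE rankings, forecast growth rates — is invariant to this
  level shift, so realism of the prevalence level is traded for the
  specified income spread without affecting what the tests measure.
- **Rejection, not truncation.** A country whose simulated prevalence
  exits $(0, 100)$ anywhere is redrawn wholesale; truncating would distort
  the log-log structure the estimator assumes. Under the default
  configuration the redraw rate is well below 1%, so the effective
  generating distribution is essentially the stated one.

Strata are generated as independent coefficient draws from the shared
second stage. What the generator does **not** emulate: systematic
male–female prevalence gaps, correlation of strata within a country,
real-world prevalence marginals or income series, measurement error in
prevalence estimates, or moderators that co-move with income. Passing
recovery tests therefore demonstrate correctness of the estimation
machinery under the model's own assumptions, not robustness to the ways
real WHO/World Bank data violate them.

## Numerical choices and degenerate inputs

- Country-coefficient conditionals are solved via symmetric-positive-
  definite inverses of 2×2 precisions; the sampler initializes at
  per-country least squares with a $10^{-8}$ ridge.
- The generator accepts positive semi-definite $\Sigma$ (including zero)
  so the noiseless identifiability check — with $\sigma_y = 0$ and
  $\Sigma = 0$ the two-step pipeline recovers $\theta_\beta$ to numerical
  tolerance — is expressible.
- MAPE ties within $10^{-9}$ are flagged and resolved in favor of the
  first-listed form (relevant when nested forms both interpolate
  noiseless data).
- A lag-window spectral estimate can go negative on strongly alternating
  segments; the implementation falls back to the lag-0 autocovariance in
  that case.
- Credible intervals are equal-tailed percentiles, matching the
  (lower, upper) presentation conventional for this model class, not
  highest-density regions.

## Problem sizes used in the shipped checks

The package's simulation-based checks run at: 50 replicates of the
147×40 default panel with 5,000-iteration chains for parameter recovery;
100 replicates each for the functional-form contest and the two
forward-selection simulations; 1,000 chains of length 2,000 for Geweke
calibration. These sizes give the acceptance properties comfortable
Monte-Carlo margins while keeping a full test run to a few minutes.

## Known limitations

- In-sample MAPE rewards the quadratic's extra parameter; the contest is
  meaningful for the log-log-vs-linear comparison and on noiseless data.
- No smearing correction on the log-log back-transform (negligible at the
  noise levels considered, but a bias in principle).
- The two-step selection response ignores the differing precision of
  per-country OLS elasticities; the final inference step (the full Gibbs
  refit) does not inherit this approximation.
- Forecasts hold the moderator-driven elasticity structure fixed and vary
  only the scenario multipliers; structural change in the moderators
  themselves is out of scope.
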