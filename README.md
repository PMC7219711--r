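# obelast — income elasticity of adult obesity prevalence

`obelast` estimates how national adult obesity prevalence responds to
national income, for epidemiologists and health economists working with
country-year panels of prevalence (percent of adults with BMI > 30 kg/m²)
and GDP per capita (GDPPC). Its core is a two-stage Bayesian hierarchical
random-coefficients model:

```
stage 1 (within country):   ln(prev_ct) = α_c + β_c · ln(GDPPC_ct) + ε_ct,   ε_ct ~ N(0, σ_c²)
stage 2 (across countries): (α_c, β_c)  = (x_c'θ_α, x_c'θ_β) + π_c,          π_c ~ MVN(0, Σ)
```

The slope β_c is the **income elasticity of obesity prevalence** — the
percent change in prevalence per 1% change in GDPPC. The second stage
regresses the country intercepts and elasticities on standardized
macro-environmental moderators organized into five dimensions
(globalization, demographic, economic, labor market, health policy), so the
coefficients θ_β measure how each moderator strengthens or weakens the
income–obesity relationship. Both stages are estimated jointly by a
conjugate Gibbs sampler (normal / inverse-gamma / matrix-normal /
inverse-Wishart full conditionals, implemented in RcppArmadillo).

Around that core the package provides the full workflow:

- **Panel I/O and validation** (`read_panel`, `validate_panel`,
  `standardize_moderators`, `compute_cagr`, `group_summary`)
- **Functional-form contest** — per-country OLS fits of linear, quadratic
  and log-log forms compared by mean absolute percentage error on the
  common percent scale (`form_contest`)
- **Moderator forward selection** under AIC/BIC with a pairwise-correlation
  screen, guaranteeing at least one variable per dimension
  (`forward_select`)
- **Convergence diagnostics** — Geweke Z-scores with a lag-windowed
  spectral variance estimate (`geweke_diagnostic`, `geweke_table`)
- **Forecasting** — prevalence trajectories compounded from posterior
  elasticity draws and projected income growth, with five sensitivity
  scenarios including gradual elasticity declines (`run_scenarios`)
- **Synthetic data generation** with recorded ground truth for
  parameter-recovery testing (`generator_config`, `generate_panel`)
- **One-call orchestration** (`run_full_analysis`)

## Worked example

```r
library(obelast)

# a synthetic 147-country x 40-year panel with known truth
cfg  <- generator_config(strata = "overall")          # true mean elasticity 1.2
mods <- standardize_moderators(generate_moderators(cfg, seed = 11))
gen  <- generate_panel(cfg, mods, seed = 12)

# which functional form fits best?
form_contest(gen$panel)$mape_table
#>        form     mape
#> 1    linear 4.289301
#> 2 quadratic 3.901554
#> 3    loglog 3.919880

# fit the hierarchical model and summarize
fit <- run_gibbs(gen$panel, mods,
                 mcmc = mcmc_config(n_iter = 5000, burn_in = 2500,
                                    thin = 5, seed = 13))
summarize_posterior(fit)
#> Two-stage hierarchical model summary (stratum: overall, 500 draws)
#> Cross-country mean elasticity: 1.194 (1.186, 1.201)
#>
#> Second-stage coefficients (elasticity equation):
#>     variable estimate  lower  upper significant
#>  (Intercept)    1.185  1.113  1.254        TRUE
#>          m01    0.044  0.001  0.090        TRUE
#>          m02   -0.094 -0.140 -0.050        TRUE
#>          m03   -0.061 -0.104 -0.017        TRUE
#>          m04    0.024 -0.023  0.074       FALSE
#>          ...
```

The mean elasticity of 1.194 recovers the generating value 1.2: a 1% rise
in GDP per capita is associated with roughly a 1.2% rise in obesity
prevalence in this synthetic world. The three moderators with sizeable
generating effects (m01, m02, m03) are the ones flagged significant, with
the right signs. The MAPE table shows the in-sample fit of each candidate
form on the percent scale; the log-log form beats the linear one, and the
quadratic's small edge over log-log reflects its extra per-country
parameter, which is why the contest is read alongside the
noiseless-recovery tests rather than alone.

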