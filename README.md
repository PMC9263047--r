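# apcprev

Bayesian age-period-cohort (APC) modelling and projection of overweight
and obesity prevalence from repeated cross-sectional health interview
surveys.

## What it does, and for whom

Epidemiologists projecting the burden of overweight (BMI ≥ 25 kg/m²) and
obesity (BMI ≥ 30 kg/m²) usually have nothing better than a handful of
cross-sectional survey waves, plus official population projections by age
and sex. `apcprev` turns that into probabilistic forecasts. Cases per
age band *i* and period *j* are modelled as

```
y_ij ~ Binomial(N_ij, expit(η_ij)),    η_ij = μ + α_i + β_j + γ_k + x'b,
```

with cohort index `k = M(I − i) + j`. The age, period and cohort effects
α, β, γ carry intrinsic second-order random-walk (RW2) priors built on
each axis's numeric locations, so irregular survey spacing and unequal
age-band widths are handled in the prior; precisions have Gamma(1,
0.00005) priors; categorical covariates (sex, education, income
quintile, urbanisation, nationality) enter as fixed effects. Sum-to-zero
constraints on all three effects plus a zero-linear-trend constraint on
the cohort effect resolve the structural APC non-identifiability. Survey
design weights enter through Kish effective cell counts. Posterior
sampling is a purpose-built Metropolis-within-Gibbs scheme (conjugate
precision updates; Laplace-proposal independence MH for the latent
field). On top of the fit the package provides DIC/WAIC model
comparison, RW2 forecasting of period and cohort effects, projection
against a population table with per-100,000 rates, exceedance
probabilities `P(y_{t+x} > (1+m) y_t)`, age-structure shares, and
R²/RMSE validation.

Because real health-interview microdata are access-restricted, the
package includes a seeded generator that simulates the whole survey
(waves, covariates, stratum weights, outcomes from a known logit-linear
truth, and a synthetic population projection), so the full pipeline is
testable against ground truth.

## Worked example

```r
library(apcprev)

grid    <- apc_grid()                      # 16 bands x 6 waves x 21 cohorts
truth   <- make_truth(grid, "obese")       # known logit-linear truth
records <- simulate_survey(truth, apc_design(n_per_wave = 5000), grid, seed = 1)

counts <- aggregate_cells(records[records$sex == "man", ], grid, "obese",
                          strata = NULL, weighting = "effective")
fit <- fit_apc(counts, grid, seed = 1)
fit
#> Bayesian APC fit: effects {age, period, cohort}
#> 2000 posterior draws; MH acceptance 0.87; max split-Rhat 1.002

head(subset(effect_summaries(fit), effect == "age"), 5)
#>   effect level median lower upper   or or_lower or_upper
#> 2    age 18-25  0.000 0.000  0.00 1.00     1.00     1.00
#> 3    age 26-30  0.745 0.475  1.10 2.11     1.61     2.99
#> 4    age 31-35  1.192 0.848  1.61 3.29     2.34     4.99
#> 5    age 36-40  1.529 1.183  1.96 4.61     3.26     7.13
#> 6    age 41-45  1.884 1.499  2.34 6.58     4.48    10.42

pop  <- simulate_population_projection(grid, 1997:2030, seed = 1)
proj <- project_prevalence(fit, pop, c(grid$periods, 2019:2030),
                           sex = "man", seed = 1)
exceedance_table(proj)
#>    outcome sex year margin probability
#> 1    obese man 2025   0.00      0.9005
#> 2    obese man 2025   0.05      0.8355
#> ...
#> 7    obese man 2030   0.00      0.8955
#> 12   obese man 2030   1.00      0.0340

round(quantile(proj$rate[, "2030"], c(.025, .5, .975)))
#>  2.5%   50% 97.5%
#>  9591 17626 29123
```

Read: the age-effect odds ratios (vs the 18–25 reference band) rise
steeply into middle age; under this synthetic truth the posterior
probability that the male obesity rate in 2030 exceeds its modelled 2018
level is ~0.90, and the projected 2030 rate is 17,626 per 100,000 with a
wide 95% credible interval — forecast uncertainty grows with the
horizon, as the RW2 prior intends.

The whole analysis can also be driven from one configuration via
`apc_pipeline()` (stages `simulate`, `summarize`, `fit`, `select`,
`project`, `report`, each writing CSV artifacts plus a JSON manifest
with the seed and config hash), or from a shell through the thin wrapper
`inst/scripts/apcprev.R`.

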