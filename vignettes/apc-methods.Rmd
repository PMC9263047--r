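---
title: "Bayesian age-period-cohort modelling and projection of overweight and obesity"
author: "apcprev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian age-period-cohort modelling and projection of overweight and obesity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcprev)
```

## The problem

Repeated cross-sectional health interview surveys are often the only
long-run source of population anthropometry. The prevalence of overweight
(BMI ≥ 25 kg/m²) and obesity (BMI ≥ 30 kg/m²) in such data varies along
three entangled axes: age at interview, calendar period, and birth cohort
(generation). Because cohort = period − age, the three axes are linearly
dependent and a naive decomposition is not identifiable. Age-period-cohort
(APC) models address this by smoothing each axis and constraining the
redundant directions, and a Bayesian treatment yields directly
interpretable statements about the future, e.g. "the probability that the
obesity rate in 2030 exceeds its 2018 level by more than 10%".

`apcprev` implements this pipeline end to end: microdata derivation,
aggregation, a hierarchical Bayesian binomial APC model with RW2 priors,
DIC/WAIC model comparison, RW2 forecasting, projection against a
population forecast, and exceedance probabilities. Because real
health-interview microdata are typically access-restricted, the package
ships a seeded synthetic-data generator that emulates the survey design,
so every stage is testable against a known truth.

## The model

Cases in age band $i$ and period $j$ are modelled binomially,

$$y_{ij} \sim \mathrm{Binomial}\!\left(N_{ij}, \mathrm{expit}(\eta_{ij})\right),
\qquad \eta_{ij} = \mu + \alpha_i + \beta_j + \gamma_k + x_{ij}^\top b,$$

where $k = M(I-i)+j$ indexes the birth cohort ($M$ periods per age band,
$I$ age bands), $\mu$ is an intercept, and $b$ are optional fixed effects
(sex, education, income quintile, urbanisation, nationality) with
normal(0, 10²) priors.

**Survey weights.** Design weights enter through Kish effective counts:
each cell's denominator is the effective sample size
$(\sum w)^2/\sum w^2$ and its numerator the weighted prevalence times that
size. This keeps the binomial information content honest for clustered,
stratified designs without modelling the sampling frame; a crude
(unweighted) mode is retained for testing. The binomial kernel is
evaluated continuously ($y\log p + (N-y)\log(1-p)$) so non-integer
effective counts are valid.

**RW2 priors on irregular grids.** Each of $\alpha, \beta, \gamma$
carries an intrinsic second-order random-walk prior built from second
divided differences on the axis's numeric locations (band midpoints,
calendar years, cohort-bin midpoints) with trapezoidal inter-knot
weights, so the quadratic penalty approximates the integrated squared
second derivative at any spacing. The first age band (18–25) is wider
than the rest and the survey years are unevenly spaced, which is exactly
the situation this construction handles; at unit spacing it reduces to
the classic $\{1,-4,6,-4,1\}$ stencil. The structure matrix has rank
$n-2$; the log-density uses that deficient rank. The precision of each
effect has a Gamma(1, 0.00005) prior — the log-gamma convention on the
precision; the phrase "scale and shape of 1 and 0.00005" in the survey
literature is ambiguous, and we document this reading prominently.
The structure matrix is not rescaled to generalized unit variance; the
hyperprior refers to the raw divided-difference penalty.

**Identifiability.** The effects are constrained by sum-to-zero on all
three axes plus a zero-linear-trend constraint on the cohort effect,
attributing the common drift to the period axis, following established
APC practice for projection models. Effects are parameterised directly
in the constrained subspace, so every posterior draw satisfies the
constraints exactly rather than approximately. The intercept is
effectively flat (precision $10^{-6}$).

**Cohort binning.** With the default grid (16 bands, 6 periods, $M=1$)
the integer map $k = M(I-i)+j$ yields exactly 21 cohorts, matching
five-year bins (1895, 1900] … (1995, 2000]; the bin midpoints are the
RW2 locations, so irregular spacing is handled in the prior while the
integer map keeps the bookkeeping. Respondent birth year is survey year
minus age (the survey records age, not birth date).

## Posterior computation

The paper-scale data make the latent field small (about 50 dimensions:
intercept, fixed effects, and constrained effect coordinates), so the
sampler uses dense linear algebra and two alternating moves:

1. **Gibbs for precisions.** Conditional on an effect vector $x$,
   $\tau \mid x \sim \mathrm{Gamma}(a + r/2,\; c + x^\top Q x/2)$ with
   $r = n-2$ the penalty rank.
2. **Independence MH for the latent field.** Given the precisions, a
   Newton iteration from a fixed starting point finds the conditional
   mode and curvature of the log-concave binomial posterior; a proposal
   is drawn from that Gaussian (a Laplace approximation) and accepted by
   the exact posterior ratio. Because the proposal depends on the current
   state only through the precisions, the move is a valid
   Metropolis-within-Gibbs step. For survey-sized counts the posterior is
   close to Gaussian and acceptance rates are typically around 0.9.

Convergence is monitored by split-chain scale reduction and a crude
effective sample size on the intercept, fixed effects and log-precisions;
`fit_apc()` errors on failure unless told otherwise. Default runs use
2,500 iterations with 500 burn-in; the recovery analyses in the test
suite use 1,100/300, which gives effectively independent draws at this
model size while keeping a full six-wave fit around two minutes.

DIC uses the deviance at the posterior mean of the *linear predictor*,
the usual focus for latent Gaussian models — DIC is
parameterisation-dependent, so this choice is stated rather than implied.
WAIC is computed from the pointwise log-likelihood matrix with a
log-sum-exp guard, in cell blocks to bound memory. The absolute scale of
both criteria depends on the weighting internals of the data at hand;
only differences between variants fitted to the same cells are
meaningful, and that is all the package claims.

## Forecasting and projection

Future period effects are drawn per posterior draw from the conditional
Gaussian of the extended RW2 (annual nodes after the last survey year),
using that draw's effect values and precision; as the precision grows the
forecast collapses onto linear extrapolation of the latest trend, which
is the behaviour that makes RW2 (rather than RW1) the standard projection
prior. Cohorts entering the youngest bands after the observation window
get forecast effects on extended five-year bins, assigned by birth year
= year − band midpoint (the integer index map only covers the observed
window). Years inside the observation window reuse the fitted per-cell
linear predictor unchanged, so in-sample "projection" reproduces the
fitted rates exactly — a tested invariant.

Projected prevalence is combined with an external population projection
(only age and sex are available as strata in demography tables, so
forecasting fits are stratified by sex and contain no other covariates).
Rates per 100,000 are population-weighted over age bands per draw.
The exceedance probability
$P\left(y_{t+x} > (1+m)\,y_t\right)$ is the fraction of *paired* joint
posterior draws exceeding the threshold; the base-year value is the
per-draw modelled rate in the final observed year, not its posterior
median, so base-year uncertainty propagates. Monotonicity in $m$ is a
property of the definition and is asserted, not enforced. Whether the
probabilities refer to rates or counts is configurable in principle;
rates are the default, and with a fixed population denominator per year
the two agree up to scale.

## The synthetic-data generator

The generator defines the study conditions: six waves (1997, 2001, 2004,
2008, 2013, 2018) of 10,000 adults aged 18+, a smooth adult age pyramid,
wave-level categorical covariate distributions that drift secularly
(education and income up, non-EU share up), stratum-level (sex × age
band) survey weights, and Bernoulli outcomes from a logit-linear truth.
The default parametric truth has a concave age curve peaking near 57
years, a rising period trend (~0.03 logit/year) and a gentle cohort wave,
with fixed-effect odds ratios of the size reported for national adult
surveys (e.g. women vs men ~0.55 for overweight, superior vs no education
~0.49 for obesity); an RW2-process truth with configurable increment
variances is available for property tests. Curves are centred with the
same constraints the model uses, so truth and estimate share a scale.

Height and weight are back-filled from the simulated binary flags (BMI
uniform within the implied category, sex-specific normal heights), which
keeps the microdata schema complete without an anthropometry model —
consequently BMI *distributions* are not realistic, only the category
flags are. The generator also omits household clustering, nonresponse,
and item missingness; passing recovery tests therefore demonstrate
correctness of the inferential machinery under the stated design, not
robustness to every feature of real survey data. Within one simulated
respondent set, only the outcome used to generate the flags follows its
configured truth exactly; the other category is implied by the
back-filled BMI.

## Numerical choices and degenerate inputs

* Duplicate axis locations are rejected when building RW2 structures;
  constraint matrices are checked for full row rank.
* Cells with no respondents are carried with $N=0$, contribute zero
  likelihood, and are flagged unobserved.
* The independence proposal's Newton iteration includes step-halving,
  relevant only in the first iterations before the mode stabilises.
* A ridge of $10^{-8}$ on effect blocks keeps the joint prior precision
  positive definite; it is an explicit part of the prior, additive and
  independent of the smoothing precisions, so the Gibbs step remains
  exact.
* Effect draws are stored as full vectors (constraints applied by
  construction), so summaries never need post-hoc projection.
* Cohort-bin assignment uses half-open intervals (lower, upper]; a birth
  year at or below the lowest bin's lower edge is a coverage error that
  requires rebuilding the grid rather than silent clamping.

## Problem sizes used in the tests

Unit and property tests run on a compact grid (4 bands × 3 periods) with
waves of 800–2,500 respondents. The recovery analysis runs at the study
scale — six waves of 10,000 with all five covariates — with the
reduced-draw sampler (1,100 iterations); the model-ordering study uses
20 replicates of 1,500 respondents per wave on the compact grid. These
sizes give Monte-Carlo error comfortably below the asserted tolerances
while keeping the full suite in a few minutes.

## Known limitations

* The engine is a purpose-built sampler, not a general PPL; model
  variants are limited to subsets of {age, period, cohort} plus
  categorical fixed effects.
* DIC/WAIC magnitudes are not comparable across different weighting
  schemes or datasets.
* The exceedance statistic assumes the posterior draws are exchangeable
  paired samples; thinned or multi-chain draws must be concatenated
  consistently.
* Age bands are closed integer ranges and the oldest band is open-ended
  in spirit but capped at 100 years internally; respondents older than
  the cap are rejected rather than absorbed.

## A worked example

```{r example, eval = FALSE}
library(apcprev)

grid <- apc_grid()
truth <- make_truth(grid, "obese")
records <- simulate_survey(truth, apc_design(n_per_wave = 5000), grid,
                           seed = 1)

counts <- aggregate_cells(records[records$sex == "man", ], grid, "obese",
                          strata = NULL, weighting = "effective")
fit <- fit_apc(counts, grid, seed = 1)
effect_summaries(fit)

pop <- simulate_population_projection(grid, 1997:2030, seed = 1)
proj <- project_prevalence(fit, pop, c(grid$periods, 2019:2030),
                           sex = "man", seed = 1)
exceedance_table(proj)
plot_fan_chart(proj)
```
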