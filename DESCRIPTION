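Package: apcprev
Title: Bayesian Age-Period-Cohort Modelling and Projection of Overweight and Obesity Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing and forecasting the prevalence of overweight
    and obesity from repeated cross-sectional health interview surveys using
    Bayesian hierarchical age-period-cohort (APC) models. Provides derivation
    of body-mass-index categories and equivalized household income from survey
    microdata, aggregation into age-by-period cells with Kish effective sample
    sizes, intrinsic second-order random-walk (RW2) smoothing priors on
    irregular grids, a Markov chain Monte Carlo sampler for the binomial logit
    APC model with fixed covariate effects, DIC/WAIC model comparison,
    RW2-based forecasting of period and cohort effects, prevalence and case
    projections against population forecasts, exceedance probabilities for
    future increases, and a synthetic-data generator emulating a stratified
    multi-wave survey so the full pipeline is testable without restricted
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
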