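#' Simulation truth for the APC generator
#'
#' Realises the age, period and cohort curves of a known logit-linear truth
#' on the grid locations, together with fixed covariate effects and an
#' intercept. Two kinds are available: `"parametric"` builds smooth curves
#' shaped like a national adult-obesity surface (prevalence peaking in
#' middle age, rising over calendar time, mild cohort waves) and
#' `"rw2"` draws each curve from an intrinsic RW2 process with the given
#' increment variance. All curves are centred: sum-to-zero on every axis
#' and, for the cohort curve, zero linear trend in birth year, attributing
#' the common drift to the period axis — the same identification used by
#' the fitting machinery, so truth and estimates share a scale.
#'
#' @param grid An [apc_grid()].
#' @param outcome `"overweight"` or `"obese"` (selects default intercept and
#'   fixed effects).
#' @param kind `"parametric"` or `"rw2"`.
#' @param sigma2 Named increment variances for `kind = "rw2"`
#'   (`age`, `period`, `cohort`).
#' @param seed Integer seed (used by `kind = "rw2"`).
#' @return Object of class `apc_truth`: list with `alpha`, `beta`, `gamma`
#'   (centred curves on the grid locations), `intercept` (log-odds),
#'   `fixed` (named log-odds-ratios vs the reference levels), `outcome`.
#' @export
make_truth <- function(grid, outcome = c("obese", "overweight"),
                       kind = c("parametric", "rw2"),
                       sigma2 = c(age = 0.01, period = 0.01, cohort = 0.01),
                       seed = NULL) {
  outcome <- match.arg(outcome)
  kind <- match.arg(kind)
  loc <- grid$locations

  if (kind == "parametric") {
    # Concave age curve peaking near 57 years, rising period trend over the
    # observation window, gentle cohort wave; amplitudes on the logit scale
    # chosen to match the order of magnitude of national adult surveys
    # (odds ratios vs the youngest band of ~2-4 at the peak, ~1.8 period
    # odds growth over two decades).
    alpha <- 1.3 - 2.2 * ((loc$age - 57) / 40)^2
    beta <- 0.03 * (loc$period - min(loc$period))
    gamma <- 0.25 * sin(2 * pi * (loc$cohort - min(loc$cohort)) / 70)
  } else {
    if (!is.null(seed)) set.seed(seed)
    draw_rw2 <- function(x, s2) {
      if (s2 == 0) return(numeric(length(x)))
      S <- rw2_structure(x)
      e <- eigen(S$Q, symmetric = TRUE)
      pos <- e$values > max(e$values) * 1e-9
      # x ~ N(0, s2 * Q^+): second divided differences then have variance s2
      drop(e$vectors[, pos, drop = FALSE] %*%
             (stats::rnorm(sum(pos)) * sqrt(s2 / e$values[pos])))
    }
    alpha <- draw_rw2(loc$age, sigma2[["age"]])
    beta <- draw_rw2(loc$period, sigma2[["period"]])
    gamma <- draw_rw2(loc$cohort, sigma2[["cohort"]])
  }

  alpha <- apply_constraints(alpha, constraint_matrix(loc$age, "sum"))
  beta <- apply_constraints(beta, constraint_matrix(loc$period, "sum"))
  gamma <- apply_constraints(gamma, constraint_matrix(loc$cohort, c("sum", "trend")))

  fixed <- if (outcome == "obese") {
    c(sexwoman = log(0.97),
      educationlower_secondary = log(0.93), educationhigher_secondary = log(0.74),
      educationsuperior = log(0.49),
      income_q2 = log(1.12), income_q3 = log(1.14), income_q4 = log(0.95),
      income_q5 = log(0.83),
      urbanisationsuburban = log(0.99), urbanisationurbanized = log(1.00),
      urbanisationrural = log(1.04),
      nationalityEU = log(1.02), nationalitynon_EU = log(0.97))
  } else {
    c(sexwoman = log(0.55),
      educationlower_secondary = log(1.00), educationhigher_secondary = log(0.92),
      educationsuperior = log(0.67),
      income_q2 = log(1.17), income_q3 = log(1.09), income_q4 = log(1.09),
      income_q5 = log(0.92),
      urbanisationsuburban = log(1.02), urbanisationurbanized = log(1.05),
      urbanisationrural = log(1.10),
      nationalityEU = log(1.06), nationalitynon_EU = log(1.14))
  }
  intercept <- if (outcome == "obese") stats::qlogis(0.115) else stats::qlogis(0.42)

  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 intercept = intercept, fixed = fixed, outcome = outcome,
                 kind = kind),
            class = "apc_truth")
}

#' Survey design settings for the generator
#'
#' @param survey_years Survey waves (default the six waves 1997-2018).
#' @param n_per_wave Respondents per wave (default 10,000, the approximate
#'   net sample of one national wave).
#' @param p_woman Proportion of women per wave.
#' @return List of class `apc_design`.
#' @export
apc_design <- function(survey_years = c(1997L, 2001L, 2004L, 2008L, 2013L, 2018L),
                       n_per_wave = 10000L, p_woman = 0.53) {
  stopifnot(n_per_wave >= 0)
  structure(list(survey_years = as.integer(survey_years),
                 n_per_wave = as.integer(n_per_wave), p_woman = p_woman),
            class = "apc_design")
}

# Adult age distribution: a smooth pyramid declining after 50, emulating a
# national adult age structure.
.age_probs <- function(ages) {
  p <- exp(-pmax(ages - 50, 0)^2 / (2 * 28^2)) * exp(-pmax(40 - ages, 0) / 80)
  p / sum(p)
}

#' Simulate one repeated cross-sectional survey
#'
#' Draws respondents wave by wave: age from a smooth adult pyramid, sex,
#' education, income quintile, urbanisation and nationality from wave-level
#' categorical distributions (secularly shifting towards higher education
#' and income, as in national surveys), then a Bernoulli overweight/obesity
#' outcome with success probability
#' `expit(intercept + alpha_age + beta_period + gamma_cohort + fixed effects)`
#' where the respondent's cohort is their birth year (`year - age`) binned
#' on the grid's cohort axis. Height and weight are back-filled to be
#' consistent with the simulated flags: BMI is drawn uniformly inside the
#' implied category, height from a sex-specific normal, and weight solved
#' from the two. Survey weights are stratum-level (sex x age band) relative
#' weights, fixed per stratum given the seed.
#'
#' @param truth An [make_truth()] object.
#' @param design An [apc_design()].
#' @param grid The [apc_grid()] shared with `truth`.
#' @param seed Integer seed; the full record set is deterministic given it.
#' @return Microdata data frame with the standard columns plus derived
#'   `bmi`, `overweight`, `obese` and the respondent's true linear
#'   predictor `eta_true`.
#' @export
simulate_survey <- function(truth, design, grid, seed = 1L) {
  set.seed(seed)
  if (!identical(as.integer(design$survey_years), grid$periods))
    stop("design survey years must match the grid periods")
  n <- design$n_per_wave
  if (n == 0) {
    empty <- utils::read.csv(text = paste(
      "year,age,sex,education,income_q,urbanisation,nationality,",
      "height_m,weight_kg,weight_survey", sep = ""))
    return(empty)
  }

  ages_support <- grid$age_bands$lower[1]:grid$age_bands$upper[grid$I]
  # stratum-level relative weights (sex x band), fixed for the whole run
  wts <- matrix(stats::rgamma(2 * grid$I, shape = 12, rate = 12),
                nrow = 2, dimnames = list(c("man", "woman"), NULL))

  waves <- lapply(seq_along(design$survey_years), function(jw) {
    yr <- design$survey_years[jw]
    frac <- (jw - 1) / max(length(design$survey_years) - 1, 1)
    age <- sample(ages_support, n, replace = TRUE, prob = .age_probs(ages_support))
    sex <- ifelse(stats::runif(n) < design$p_woman, "woman", "man")
    edu_p <- c(0.22, 0.21, 0.28, 0.29) + frac * c(-0.11, -0.04, 0.03, 0.12)
    education <- sample(c("none_primary", "lower_secondary", "higher_secondary",
                          "superior"), n, TRUE, prob = edu_p / sum(edu_p))
    inc_p <- c(0.24, 0.20, 0.20, 0.18, 0.18) + frac * c(-0.09, -0.04, 0, 0.06, 0.07)
    income_q <- sample(1:5, n, TRUE, prob = inc_p / sum(inc_p))
    urbanisation <- sample(c("big_city", "suburban", "urbanized", "rural"),
                           n, TRUE, prob = c(0.48, 0.13, 0.22, 0.17))
    nat_p <- c(0.87, 0.07, 0.06) + frac * c(-0.07, 0.02, 0.05)
    nationality <- sample(c("Belgian", "EU", "non_EU"), n, TRUE,
                          prob = nat_p / sum(nat_p))

    i <- age_band_index(age, grid)
    k <- assign_cohort_bin(yr - age, grid$cohort_bins)
    eta <- truth$intercept + truth$alpha[i] + truth$beta[jw] + truth$gamma[k] +
      ifelse(sex == "woman", truth$fixed[["sexwoman"]], 0) +
      unname(c(0, truth$fixed[["educationlower_secondary"]],
               truth$fixed[["educationhigher_secondary"]],
               truth$fixed[["educationsuperior"]])[match(education,
                 c("none_primary", "lower_secondary", "higher_secondary", "superior"))]) +
      unname(c(0, truth$fixed[["income_q2"]], truth$fixed[["income_q3"]],
               truth$fixed[["income_q4"]], truth$fixed[["income_q5"]])[income_q]) +
      unname(c(0, truth$fixed[["urbanisationsuburban"]],
               truth$fixed[["urbanisationurbanized"]],
               truth$fixed[["urbanisationrural"]])[match(urbanisation,
                 c("big_city", "suburban", "urbanized", "rural"))]) +
      unname(c(0, truth$fixed[["nationalityEU"]],
               truth$fixed[["nationalitynon_EU"]])[match(nationality,
                 c("Belgian", "EU", "non_EU"))])
    yout <- stats::runif(n) < stats::plogis(eta)

    # anthropometry back-fill consistent with the simulated outcome flags
    bmi <- if (truth$outcome == "obese") {
      ifelse(yout, stats::runif(n, 30, 45), stats::runif(n, 19, 30))
    } else {
      ifelse(yout, stats::runif(n, 25, 42), stats::runif(n, 18.5, 25))
    }
    height <- round(ifelse(sex == "woman", stats::rnorm(n, 1.65, 0.065),
                           stats::rnorm(n, 1.77, 0.07)), 2)
    height <- pmin(pmax(height, 1.40), 2.10)
    weight <- round(bmi * height^2, 1)

    data.frame(year = yr, age = age, sex = sex, education = education,
               income_q = income_q, urbanisation = urbanisation,
               nationality = nationality, height_m = height,
               weight_kg = weight,
               weight_survey = wts[cbind(match(sex, c("man", "woman")), i)],
               eta_true = eta, stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, waves)
  fl <- bmi_flags(rec$height_m, rec$weight_kg)
  rec$bmi <- fl$bmi; rec$overweight <- fl$overweight; rec$obese <- fl$obese
  rec
}

#' Simulate a population-projection table
#'
#' A synthetic stand-in for official demography projections: smooth positive
#' counts per year x age band x sex, from a baseline pyramid grown at a
#' constant annual rate. Clearly synthetic; it carries no information about
#' any real national projection.
#'
#' @param grid An [apc_grid()].
#' @param years Projection years (may include the observation window).
#' @param growth Annual growth rate (default 0.004).
#' @param base_total Total adult population in the first year (default
#'   9e6, an adult-population order of magnitude).
#' @param seed Integer seed (small smooth perturbations of the pyramid).
#' @return Data frame (`year`, `age_band`, `sex`, `population`), one row per
#'   combination.
#' @export
simulate_population_projection <- function(grid, years, growth = 0.004,
                                           base_total = 9e6, seed = 1L) {
  if (!length(years)) stop("years must be non-empty")
  set.seed(seed)
  shares <- .age_probs(grid$age_bands$midpoint) *
    (grid$age_bands$upper - grid$age_bands$lower + 1)
  shares <- shares * exp(stats::rnorm(grid$I, 0, 0.02))
  shares <- shares / sum(shares)
  base <- base_total * shares / 2  # per sex
  out <- expand.grid(year = years, age_band = grid$age_bands$label,
                     sex = c("man", "woman"), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  ib <- match(out$age_band, grid$age_bands$label)
  out$population <- base[ib] * (1 + growth)^(out$year - min(years))
  out
}
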