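#' Project prevalence and case counts to a future horizon
#'
#' Combines a fitted APC model with RW2 forecasts of the period and cohort
#' effects and an external population projection. For years inside the
#' observation window the fitted per-cell linear predictor is reused
#' unchanged, so in-sample "projections" reproduce the fitted rates
#' exactly. For future years, each posterior draw is extended with its own
#' conditional RW2 forecast: future period nodes are annual steps after the
#' last survey year, and cohorts entering the youngest bands get
#' forecast cohort effects on extended five-year bins (assigned by birth
#' year = year - band midpoint). Only strata available in the demography
#' table (age band, sex) enter the forecast, so the fit must not contain
#' fixed covariates; sex enters by fitting per sex.
#'
#' @param fit An [fit_apc()] object with effects age + period + cohort and
#'   no fixed covariates (a per-sex fit).
#' @param population Population projection data frame (`year`, `age_band`,
#'   `sex`, `population`) covering every requested year and band.
#' @param years Integer years to project (may include observed years).
#' @param sex Which sex the fit describes (used to filter `population`).
#' @param seed Integer seed for the forecast noise.
#' @return Object of class `apc_projection`: arrays `prev` and `cases`
#'   indexed `[draw, year, band]`, matrix `rate` (per 100,000, draws x
#'   years, population-weighted over bands), and a `summary` data frame
#'   with median and 2.5/25/75/97.5% quantiles per year x band.
#' @export
project_prevalence <- function(fit, population, years, sex = "man", seed = 1L) {
  grid <- fit$grid
  if (length(fit$fixed_vars))
    stop("projection requires a fit without fixed covariates; ",
         "fit per sex instead")
  if (!all(c("age", "period", "cohort") %in% fit$effects))
    stop("projection requires age, period and cohort effects in the fit")
  years <- sort(as.integer(years))
  pop <- population[population$sex == sex, ]
  need <- expand.grid(year = years, age_band = grid$age_bands$label,
                      stringsAsFactors = FALSE)
  key <- paste(pop$year, pop$age_band)
  m <- match(paste(need$year, need$age_band), key)
  if (any(is.na(m)))
    stop("population projection missing ", sum(is.na(m)), " year x band cells")
  pop_mat <- matrix(pop$population[m], nrow = length(years),
                    dimnames = list(years, grid$age_bands$label))

  last_obs <- max(grid$periods)
  fut_years <- years[years > last_obs]
  n_draws <- fit$n_draws
  set.seed(seed)

  # --- RW2 forecasts shared across all future cells -------------------
  beta_fut <- NULL
  if (length(fut_years)) {
    fut_nodes <- seq(last_obs + 1L, max(fut_years))
    S_ext <- rw2_structure(c(grid$locations$period, fut_nodes))
    beta_fut <- .forecast_draws(fit$beta, fit$tau[, "period"], S_ext,
                                n_obs = grid$J)
    colnames(beta_fut) <- as.character(fut_nodes)
  }

  # extended cohort bins for cohorts born after the last observed bin
  cw <- grid$cohort_bins$upper[2] - grid$cohort_bins$upper[1]
  latest_birth <- if (length(fut_years))
    max(fut_years) - min(grid$age_bands$midpoint) else -Inf
  n_new_bins <- max(0, ceiling((latest_birth - max(grid$cohort_bins$upper)) / cw))
  gamma_all <- fit$gamma
  bins_ext <- grid$cohort_bins
  if (n_new_bins > 0) {
    new_lower <- max(grid$cohort_bins$upper) + cw * (seq_len(n_new_bins) - 1L)
    bins_new <- data.frame(lower = new_lower, upper = new_lower + cw,
                           label = sprintf("(%d, %d]", new_lower, new_lower + cw),
                           midpoint = new_lower + cw / 2)
    S_cext <- rw2_structure(c(grid$locations$cohort, bins_new$midpoint))
    gamma_fut <- .forecast_draws(fit$gamma, fit$tau[, "cohort"], S_cext,
                                 n_obs = grid$K)
    gamma_all <- cbind(fit$gamma, gamma_fut)
    bins_ext <- rbind(bins_ext, bins_new)
  }

  # --- per (year, band) linear predictor draws ------------------------
  prev <- array(NA_real_, c(n_draws, length(years), grid$I),
                dimnames = list(NULL, years, grid$age_bands$label))
  for (ti in seq_along(years)) {
    t <- years[ti]
    if (t <= last_obs) {
      if (!t %in% grid$periods)
        stop("year ", t, " predates the horizon but is not a survey year")
      j <- match(t, grid$periods)
      for (i in seq_len(grid$I)) {
        k <- cohort_index(i, j, grid$M, grid$I)
        eta <- fit$intercept + fit$alpha[, i] + fit$beta[, j] + fit$gamma[, k]
        prev[, ti, i] <- stats::plogis(eta)
      }
    } else {
      bcol <- as.character(t)
      for (i in seq_len(grid$I)) {
        birth <- t - grid$age_bands$midpoint[i]
        k <- which(birth > bins_ext$lower & birth <= bins_ext$upper)
        if (length(k) != 1)
          stop("cohort born ", birth, " not covered by the forecast bins")
        eta <- fit$intercept + fit$alpha[, i] + beta_fut[, bcol] + gamma_all[, k]
        prev[, ti, i] <- stats::plogis(eta)
      }
    }
  }

  # broadcast population over draws: pop_mat is [year, band], prev flattens
  # draw-fastest, then year, then band
  cases <- prev * rep(as.vector(pop_mat), each = n_draws)
  dim(cases) <- dim(prev); dimnames(cases) <- dimnames(prev)
  denom <- rowSums(pop_mat)
  rate <- 1e5 * sweep(apply(cases, c(1, 2), sum), 2, denom, "/")

  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  summ <- do.call(rbind, lapply(seq_along(years), function(ti) {
    do.call(rbind, lapply(seq_len(grid$I), function(i) {
      qv <- stats::quantile(prev[, ti, i], qs)
      data.frame(year = years[ti], age_band = grid$age_bands$label[i],
                 sex = sex, q2.5 = qv[1], q25 = qv[2], median = qv[3],
                 q75 = qv[4], q97.5 = qv[5], row.names = NULL)
    }))
  }))

  structure(list(prev = prev, cases = cases, rate = rate, pop = pop_mat,
                 bands = grid$age_bands, years = years, sex = sex,
                 outcome = attr(fit$counts, "outcome"),
                 base_year = last_obs, summary = summ),
            class = "apc_projection")
}

# vectorised conditional RW2 forecast: one future draw per posterior draw,
# using that draw's effect vector and precision
.forecast_draws <- function(x_obs_draws, tau_draws, S_ext, n_obs) {
  n <- length(S_ext$locations)
  fut <- (n_obs + 1L):n
  Q <- S_ext$Q
  R <- chol(Q[fut, fut, drop = FALSE])
  mu <- -t(backsolve(R, backsolve(R, t(x_obs_draws %*% t(Q[fut, seq_len(n_obs),
                                                           drop = FALSE])),
                                  transpose = TRUE)))
  z <- matrix(stats::rnorm(nrow(x_obs_draws) * length(fut)), nrow(x_obs_draws))
  mu + (z %*% t(backsolve(R, diag(length(fut))))) / sqrt(tau_draws)
}

#' Exceedance probability of a projected rate
#'
#' Posterior probability that the projected rate in a target year exceeds
#' the modelled rate in the base year by more than a margin `m`, computed
#' on paired draws of the joint posterior:
#' `P(rate(t+x) > (1 + m) rate(t))`.
#'
#' @param result An [project_prevalence()] result containing both years.
#' @param base_year Base year `t` (default: last observed survey year).
#' @param target_year Future year `t + x`.
#' @param margin Relative margin `m` (e.g. `0.05` for a 5% increase).
#' @return Probability in `[0, 1]`.
#' @export
exceedance_probability <- function(result, target_year,
                                   base_year = result$base_year, margin = 0) {
  bt <- as.character(c(base_year, target_year))
  if (!all(bt %in% colnames(result$rate)))
    stop("base and target years must both be projected")
  mean(result$rate[, bt[2]] > (1 + margin) * result$rate[, bt[1]])
}

#' Exceedance probability table
#'
#' Full grid of exceedance probabilities over margins and target years.
#' Monotone non-increase in the margin is a property of the definition
#' (the same paired draws are thresholded at nested cut-offs), not a
#' post-hoc adjustment.
#'
#' @param result An [project_prevalence()] result.
#' @param margins Relative margins (default 0, 5, 10, 25, 50, 100%).
#' @param years Target years (default 2025 and 2030 when available).
#' @param base_year Base year of the comparison.
#' @return Data frame (`outcome`, `sex`, `year`, `margin`, `probability`).
#' @export
exceedance_table <- function(result,
                             margins = c(0, 0.05, 0.10, 0.25, 0.50, 1.00),
                             years = intersect(c(2025, 2030), result$years),
                             base_year = result$base_year) {
  g <- expand.grid(margin = margins, year = years, KEEP.OUT.ATTRS = FALSE)
  g$probability <- mapply(function(m, t)
    exceedance_probability(result, t, base_year, m), g$margin, g$year)
  data.frame(outcome = result$outcome, sex = result$sex,
             year = g$year, margin = g$margin, probability = g$probability)
}

#' Share of projected cases in an age range
#'
#' Posterior share of cases falling in age bands fully inside
#' `[range[1], range[2]]`; the range must align with band edges. Summarised
#' by the posterior median of the per-draw share.
#'
#' @param result An [project_prevalence()] result.
#' @param year Projected year.
#' @param range Inclusive age range, e.g. `c(36, 65)`.
#' @return List with `share` (posterior median) and `draws`.
#' @export
age_share <- function(result, year, range = c(36, 65)) {
  lower <- result$bands$lower
  upper <- result$bands$upper
  if (!range[1] %in% lower || !(range[2] %in% upper))
    stop("age range must align with band edges")
  sel <- lower >= range[1] & upper <= range[2]
  ti <- match(as.character(year), dimnames(result$cases)[[2]])
  if (is.na(ti)) stop("year ", year, " not projected")
  draws <- rowSums(result$cases[, ti, sel, drop = FALSE]) /
    rowSums(result$cases[, ti, , drop = FALSE])
  list(share = stats::median(draws), draws = draws)
}

#' Validation metrics between observed and predicted series
#'
#' Coefficient of determination `R^2 = 1 - SS_res / SS_tot` (around the
#' observed mean) and root mean squared error, for paired observed and
#' predicted prevalence values.
#'
#' @param observed Numeric vector of observed values.
#' @param predicted Numeric vector of predictions, same length >= 2.
#' @return List with `r2` and `rmse`.
#' @export
validate_projection <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("observed and predicted must be paired series of length >= 2")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed series has zero variance; R^2 undefined")
  ss_res <- sum((observed - predicted)^2)
  list(r2 = 1 - ss_res / ss_tot,
       rmse = sqrt(mean((observed - predicted)^2)))
}

#' Fan chart of modelled and projected rates
#'
#' Plots the posterior median rate per 100,000 with nested quantile bands
#' (2.5-97.5% and 25-75%) over years, marking the start of the
#' projection horizon. Requires ggplot2.
#'
#' @param result An [project_prevalence()] result.
#' @return A ggplot object.
#' @export
plot_fan_chart <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  qs <- apply(result$rate, 2, stats::quantile, c(0.025, 0.25, 0.5, 0.75, 0.975))
  df <- data.frame(year = result$years, lo95 = qs[1, ], lo50 = qs[2, ],
                   med = qs[3, ], hi50 = qs[4, ], hi95 = qs[5, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo50, ymax = .data$hi50),
                         fill = "steelblue", alpha = 0.45) +
    ggplot2::geom_line(ggplot2::aes(y = .data$med), linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = result$base_year, linetype = 2) +
    ggplot2::labs(x = "Year", y = "Rate per 100,000",
                  title = paste0(result$outcome, " (", result$sex, ")")) +
    ggplot2::theme_minimal()
}
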