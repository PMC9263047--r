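#' Gamma prior on an RW2 precision
#'
#' The smoothing precision tau of each RW2 effect carries a Gamma(shape,
#' rate) prior — equivalently a log-gamma prior on log(tau). The default
#' shape 1 and rate 0.00005 is very weakly informative, allowing the data
#' to determine each axis's smoothness.
#'
#' @param shape Gamma shape (> 0), default 1.
#' @param rate Gamma rate (> 0), default 0.00005.
#' @return List of class `precision_prior`.
#' @export
precision_prior <- function(shape = 1, rate = 0.00005) {
  stopifnot(shape > 0, rate > 0)
  structure(list(shape = shape, rate = rate), class = "precision_prior")
}

# reference levels used for dummy coding of fixed covariates
.fixed_levels <- list(
  sex = c("man", "woman"),
  education = c("none_primary", "lower_secondary", "higher_secondary", "superior"),
  income_q = as.character(1:5),
  urbanisation = c("big_city", "suburban", "urbanized", "rural"),
  nationality = c("Belgian", "EU", "non_EU")
)

# Build the dense design matrix of the latent field and the block metadata.
# Latent order: intercept, fixed-effect coefficients, then the reduced
# (constraint-free) coordinates of the age, period, cohort effects.
.build_design <- function(counts, grid, effects, fixed) {
  M <- nrow(counts)
  blocks <- list()
  Xparts <- list(intercept = matrix(1, M, 1))
  colnames(Xparts$intercept) <- "(Intercept)"

  if (length(fixed)) {
    for (v in fixed) {
      if (!v %in% names(counts))
        stop("fixed covariate '", v, "' is not a stratum column of counts; ",
             "aggregate with strata including it")
      lev <- .fixed_levels[[v]]
      if (is.null(lev)) lev <- sort(unique(as.character(counts[[v]])))
      f <- factor(as.character(counts[[v]]), levels = lev)
      if (any(is.na(f))) stop("unknown level in covariate '", v, "'")
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, lev[-1])
      Xparts[[v]] <- mm
    }
  }
  p_fixed <- sum(vapply(Xparts, ncol, 0L)) - 1L

  Tmats <- list()
  if ("age" %in% effects) {
    A <- constraint_matrix(grid$locations$age, "sum")
    Tmats$age <- .complement_basis(A)
    Z <- matrix(0, M, grid$I); Z[cbind(seq_len(M), counts$i)] <- 1
    Xparts$age <- Z %*% Tmats$age
  }
  if ("period" %in% effects) {
    A <- constraint_matrix(grid$locations$period, "sum")
    Tmats$period <- .complement_basis(A)
    Z <- matrix(0, M, grid$J); Z[cbind(seq_len(M), counts$j)] <- 1
    Xparts$period <- Z %*% Tmats$period
  }
  if ("cohort" %in% effects) {
    A <- constraint_matrix(grid$locations$cohort, c("sum", "trend"))
    Tmats$cohort <- .complement_basis(A)
    Z <- matrix(0, M, grid$K); Z[cbind(seq_len(M), counts$k)] <- 1
    Xparts$cohort <- Z %*% Tmats$cohort
  }

  X <- do.call(cbind, Xparts)
  idx <- list(); pos <- 1L
  for (nm in names(Xparts)) {
    w <- ncol(Xparts[[nm]])
    idx[[nm]] <- seq.int(pos, pos + w - 1L)
    pos <- pos + w
  }
  list(X = X, idx = idx, Tmats = Tmats, p_fixed = p_fixed,
       fixed_names = if (p_fixed > 0)
         unlist(lapply(Xparts[setdiff(names(Xparts), c("intercept", "age", "period", "cohort"))], colnames),
                use.names = FALSE) else character())
}

# prior precision matrix of the latent field for given taus
.prior_precision <- function(design, grid, effects, taus, fixed_prec,
                             intercept_prec = 1e-6) {
  d <- ncol(design$X)
  P <- matrix(0, d, d)
  P[design$idx$intercept, design$idx$intercept] <- intercept_prec
  fixed_blocks <- setdiff(names(design$idx), c("intercept", "age", "period", "cohort"))
  for (nm in fixed_blocks) {
    ii <- design$idx[[nm]]
    P[cbind(ii, ii)] <- fixed_prec
  }
  for (e in effects) {
    S <- rw2_structure(grid$locations[[e]])
    Pe <- crossprod(design$Tmats[[e]], S$Q %*% design$Tmats[[e]])
    ii <- design$idx[[e]]
    P[ii, ii] <- taus[[e]] * (Pe + t(Pe)) / 2 + diag(1e-8, length(ii))
  }
  P
}

# Newton iteration from a fixed start to the conditional mode of the latent
# field given taus; returns mode and the negative Hessian there.
.newton_mode <- function(theta0, X, y, N, P, max_iter = 50, tol = 1e-8) {
  theta <- theta0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% theta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(X, y - N * p)) - P %*% theta
    W <- N * p * (1 - p)
    H <- P + crossprod(X * sqrt(pmax(W, 0)))
    step <- solve(H, g)
    theta_new <- theta + step
    # halving to guard the few first steps
    f_old <- sum(.binom_loglik(y, N, eta, FALSE)) - 0.5 * drop(crossprod(theta, P %*% theta))
    for (h in 0:10) {
      eta_new <- drop(X %*% theta_new)
      f_new <- sum(.binom_loglik(y, N, eta_new, FALSE)) -
        0.5 * drop(crossprod(theta_new, P %*% theta_new))
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      theta_new <- theta + step / 2^(h + 1)
    }
    done <- max(abs(theta_new - theta)) < tol
    theta <- drop(theta_new)
    if (done) break
  }
  eta <- drop(X %*% theta)
  p <- stats::plogis(eta)
  W <- N * p * (1 - p)
  list(mode = theta, H = P + crossprod(X * sqrt(pmax(W, 0))))
}

#' Fit the Bayesian hierarchical APC binomial model
#'
#' Samples the joint posterior of the binomial logit model
#' `y_cell ~ Binomial(N_cell, expit(eta))` with
#' `eta = intercept + alpha_age + beta_period + gamma_cohort + X b`,
#' intrinsic RW2 priors (on the grid's irregular locations) for the
#' included random effects, Gamma priors on their precisions, and normal
#' priors on fixed effects. Identifiability is enforced by hard sum-to-zero
#' constraints on every included effect plus a zero-linear-trend constraint
#' on the cohort effect, attributing the common drift to the period axis;
#' effects are parameterised directly in the constrained subspace so every
#' draw satisfies the constraints exactly.
#'
#' The sampler alternates (i) conjugate Gibbs draws of each RW2 precision
#' given its effect vector, `tau | x ~ Gamma(shape + rank/2, rate + x'Qx/2)`
#' with the deficient rank `n - 2`, and (ii) an independence
#' Metropolis-Hastings update of the whole latent Gaussian field using a
#' Laplace proposal: a Newton iteration (from a fixed starting point, so
#' the proposal depends only on the current precisions) finds the
#' conditional mode and curvature, and a draw from that Gaussian is
#' accepted or rejected by the exact posterior ratio. For binomial counts
#' of survey size the posterior is close to Gaussian and acceptance rates
#' are high.
#'
#' Non-integer effective counts (Kish weighting) are handled through the
#' continuous binomial kernel `y log p + (N - y) log(1 - p)`.
#'
#' @param counts A `cell_counts` data frame from [aggregate_cells()].
#' @param grid The [apc_grid()] the counts were aggregated on.
#' @param effects Random effects to include, subset of
#'   `c("age", "period", "cohort")`.
#' @param fixed Fixed covariate names (must be stratum columns of `counts`),
#'   e.g. `c("sex", "education")`.
#' @param prior [precision_prior()] applied to each RW2 precision.
#' @param fixed_sd Prior standard deviation of fixed-effect log-odds
#'   (default 10, weakly informative).
#' @param n_iter Total MCMC iterations.
#' @param burnin Burn-in iterations discarded.
#' @param seed Integer seed; draws are deterministic given it.
#' @param check_convergence If `TRUE` (default), error when the split-chain
#'   scale-reduction diagnostic exceeds 1.2 on any monitored parameter
#'   rather than returning a silently unconverged fit.
#' @return Object of class `apc_fit`: posterior draw matrices `alpha`,
#'   `beta`, `gamma` (full effect vectors, constraints satisfied on every
#'   draw), `fixed`, `intercept`, `tau`; the latent draws and design; and
#'   `diagnostics` (acceptance rate, split-Rhat, effective sample sizes).
#' @export
fit_apc <- function(counts, grid,
                    effects = c("age", "period", "cohort"),
                    fixed = character(),
                    prior = precision_prior(),
                    fixed_sd = 10,
                    n_iter = 2500, burnin = 500, seed = 1L,
                    check_convergence = TRUE) {
  effects <- match.arg(effects, several.ok = TRUE)
  if (!length(effects)) stop("at least one random effect must be included")
  if (!nrow(counts) || all(counts$N == 0)) stop("no observed cells to fit")
  if (burnin >= n_iter) stop("burnin must be smaller than n_iter")
  set.seed(seed)

  keep <- counts$N > 0
  cc <- counts[keep, , drop = FALSE]
  design <- .build_design(cc, grid, effects, fixed)
  X <- design$X; y <- cc$y; N <- cc$N
  d <- ncol(X)

  Smats <- lapply(effects, function(e) rw2_structure(grid$locations[[e]]))
  names(Smats) <- effects
  Pmats <- lapply(effects, function(e)
    crossprod(design$Tmats[[e]], Smats[[e]]$Q %*% design$Tmats[[e]]))
  names(Pmats) <- effects
  ranks <- vapply(effects, function(e) Smats[[e]]$rank, 0L)

  taus <- stats::setNames(rep(10, length(effects)), effects)
  fixed_prec <- 1 / fixed_sd^2

  # fixed Newton start: mode under the initial precisions
  P0 <- .prior_precision(design, grid, effects, as.list(taus), fixed_prec)
  start <- .newton_mode(rep(0, d), X, y, N, P0)$mode
  theta <- start

  n_keep <- n_iter - burnin
  theta_draws <- matrix(NA_real_, n_keep, d)
  tau_draws <- matrix(NA_real_, n_keep, length(effects),
                      dimnames = list(NULL, effects))
  n_accept <- 0L

  log_post <- function(theta, P) {
    eta <- drop(X %*% theta)
    sum(.binom_loglik(y, N, eta, FALSE)) -
      0.5 * drop(crossprod(theta, P %*% theta))
  }

  for (it in seq_len(n_iter)) {
    # --- Gibbs: tau_e | effect vector ---------------------------------
    for (e in effects) {
      z <- theta[design$idx[[e]]]
      quad <- drop(crossprod(z, Pmats[[e]] %*% z))
      taus[[e]] <- stats::rgamma(1, shape = prior$shape + ranks[[e]] / 2,
                                 rate = prior$rate + quad / 2)
    }
    P <- .prior_precision(design, grid, effects, as.list(taus), fixed_prec)

    # --- independence MH on the latent field --------------------------
    nm <- .newton_mode(start, X, y, N, P)
    R <- chol(nm$H)
    prop <- nm$mode + drop(backsolve(R, stats::rnorm(d)))
    lq <- function(th) {
      r <- drop(R %*% (th - nm$mode))
      -0.5 * sum(r^2)  # common log-det cancels in the ratio
    }
    log_r <- (log_post(prop, P) - lq(prop)) - (log_post(theta, P) - lq(theta))
    if (is.finite(log_r) && log(stats::runif(1)) < log_r) {
      theta <- prop
      n_accept <- n_accept + 1L
    }

    if (it > burnin) {
      theta_draws[it - burnin, ] <- theta
      tau_draws[it - burnin, ] <- unlist(taus)
    }
  }

  expand <- function(e, dim_n) {
    if (!e %in% effects) return(matrix(0, n_keep, dim_n))
    theta_draws[, design$idx[[e]], drop = FALSE] %*% t(design$Tmats[[e]])
  }
  alpha <- expand("age", grid$I)
  beta <- expand("period", grid$J)
  gamma <- expand("cohort", grid$K)
  colnames(alpha) <- grid$age_bands$label
  colnames(beta) <- as.character(grid$periods)
  colnames(gamma) <- grid$cohort_bins$label
  intercept <- theta_draws[, design$idx$intercept]
  fixed_draws <- if (design$p_fixed > 0) {
    fd <- theta_draws[, setdiff(unlist(design$idx[setdiff(names(design$idx),
            c("intercept", "age", "period", "cohort"))]), integer()), drop = FALSE]
    colnames(fd) <- design$fixed_names
    fd
  } else matrix(0, n_keep, 0)

  monitored <- cbind(intercept = intercept,
                     if (ncol(fixed_draws)) fixed_draws,
                     log_tau = log(tau_draws))
  rhat <- apply(monitored, 2, .split_rhat)
  ess <- apply(monitored, 2, .ess)
  diagnostics <- list(acceptance = n_accept / n_iter, rhat = rhat, ess = ess,
                      converged = all(is.na(rhat) | rhat < 1.2))
  if (check_convergence && !diagnostics$converged)
    stop("MCMC did not converge (max split-Rhat = ",
         round(max(rhat, na.rm = TRUE), 3),
         "); increase n_iter or revisit the model",
         call. = FALSE)

  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 fixed = fixed_draws, intercept = intercept, tau = tau_draws,
                 theta = theta_draws, design = design,
                 counts = counts, grid = grid, effects = effects,
                 fixed_vars = fixed, prior = prior, seed = seed,
                 n_draws = n_keep, diagnostics = diagnostics),
            class = "apc_fit")
}

#' @export
print.apc_fit <- function(x, ...) {
  cat("Bayesian APC fit: effects {", paste(x$effects, collapse = ", "),
      "}", if (length(x$fixed_vars)) paste0(" + fixed {",
      paste(x$fixed_vars, collapse = ", "), "}"), "\n",
      x$n_draws, " posterior draws; MH acceptance ",
      round(x$diagnostics$acceptance, 2), "; max split-Rhat ",
      round(max(x$diagnostics$rhat, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

# per-cell linear predictor draws (draws x cells actually fitted)
.eta_draws <- function(fit, cells = NULL) {
  X <- fit$design$X
  if (!is.null(cells)) X <- X[cells, , drop = FALSE]
  fit$theta %*% t(X)
}

#' Posterior effect summaries and odds ratios
#'
#' Posterior medians and 2.5/97.5% quantiles per effect level, with odds
#' ratios: fixed effects against their declared reference level
#' (`exp(coef)`), random-effect levels against the first level
#' (`exp(effect - effect_ref)`, so the reference has OR exactly 1), and the
#' intercept on the odds scale.
#'
#' @param fit An [fit_apc()] object.
#' @return Data frame with columns `effect`, `level`, `median`, `lower`,
#'   `upper` (logit scale), and `or`, `or_lower`, `or_upper`.
#' @export
effect_summaries <- function(fit) {
  q3 <- function(m) t(apply(m, 2, stats::quantile, c(0.5, 0.025, 0.975)))
  rows <- list()
  add <- function(effect, draws, reference = FALSE) {
    if (reference) draws <- sweep(draws, 1, draws[, 1], "-")
    s <- q3(draws)
    o <- q3(exp(draws))
    rows[[length(rows) + 1]] <<- data.frame(
      effect = effect, level = colnames(draws),
      median = s[, 1], lower = s[, 2], upper = s[, 3],
      or = o[, 1], or_lower = o[, 2], or_upper = o[, 3],
      row.names = NULL)
  }
  add("intercept", matrix(fit$intercept, ncol = 1,
                          dimnames = list(NULL, "(Intercept)")))
  if (ncol(fit$fixed)) add("fixed", fit$fixed)
  if ("age" %in% fit$effects) add("age", fit$alpha, reference = TRUE)
  if ("period" %in% fit$effects) add("period", fit$beta, reference = TRUE)
  if ("cohort" %in% fit$effects) add("cohort", fit$gamma, reference = TRUE)
  do.call(rbind, rows)
}

.reshape_ll <- function(eta, y, N) {
  ll <- .binom_loglik(rep(y, each = nrow(eta)), rep(N, each = nrow(eta)), eta)
  dim(ll) <- dim(eta)
  ll
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - D(eta_bar)` evaluated at the posterior mean of the latent
#' linear predictor (the usual focus for latent Gaussian models; DIC is
#' parameterisation-dependent and this choice is deliberate). Deviance is
#' `-2` times the binomial log-likelihood, using the continuous kernel with
#' a `lgamma` combinatorial term so non-integer effective counts are valid.
#'
#' @param fit An [fit_apc()] object.
#' @param chunk Number of cells processed per block (memory control).
#' @return List with `dic`, `dbar`, `dhat`, `pd`.
#' @export
dic <- function(fit, chunk = 4000L) {
  keep <- which(fit$counts$N > 0)
  y <- fit$counts$y[keep]; N <- fit$counts$N[keep]
  M <- length(keep)
  dev_draws <- numeric(fit$n_draws)
  dhat <- 0
  for (s in seq(1, M, by = chunk)) {
    ii <- s:min(s + chunk - 1, M)
    eta <- .eta_draws(fit, cells = ii)
    dev_draws <- dev_draws - 2 * rowSums(.reshape_ll(eta, y[ii], N[ii]))
    dhat <- dhat - 2 * sum(.binom_loglik(y[ii], N[ii], colMeans(eta)))
  }
  dbar <- mean(dev_draws)
  pd <- dbar - dhat
  list(dic = dbar + pd, dbar = dbar, dhat = dhat, pd = pd)
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 (lppd - pWAIC)` with
#' `lppd = sum_cells log mean_draws likelihood` (computed with a
#' log-sum-exp guard) and `pWAIC = sum_cells var_draws log-likelihood`.
#' Cells with `N = 0` contribute zero.
#'
#' @param fit An [fit_apc()] object.
#' @param chunk Number of cells processed per block (memory control).
#' @return List with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(fit, chunk = 4000L) {
  keep <- which(fit$counts$N > 0)
  y <- fit$counts$y[keep]; N <- fit$counts$N[keep]
  M <- length(keep)
  lppd <- 0; p_waic <- 0
  for (s in seq(1, M, by = chunk)) {
    ii <- s:min(s + chunk - 1, M)
    eta <- .eta_draws(fit, cells = ii)
    ll <- .reshape_ll(eta, y[ii], N[ii])
    mx <- apply(ll, 2, max)
    lppd <- lppd + sum(mx + log(colMeans(exp(sweep(ll, 2, mx, "-")))))
    p_waic <- p_waic + sum(apply(ll, 2, stats::var))
  }
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Compare APC model variants by DIC and WAIC
#'
#' Fits each requested variant (`"APC"`, `"AP"`, `"AC"`, `"P"`, `"APC+F"`)
#' to the same cell counts and tabulates DIC and WAIC, flagging the minimum
#' of each and recording variants whose sampler failed the convergence
#' diagnostic instead of aborting the comparison.
#'
#' @param counts Cell counts from [aggregate_cells()].
#' @param grid The matching [apc_grid()].
#' @param variants Character vector of variant labels.
#' @param fixed Fixed covariates used by the `"APC+F"` variant.
#' @param seed Base seed; variant v uses `seed + position`.
#' @param ... Further arguments passed to [fit_apc()] (e.g. `n_iter`).
#' @return Data frame with columns `variant`, `dic`, `waic`, `converged`,
#'   `best_dic`, `best_waic`.
#' @export
model_selection <- function(counts, grid,
                            variants = c("APC", "AP", "AC", "P", "APC+F"),
                            fixed = c("sex"), seed = 1L, ...) {
  if (length(variants) < 2) stop("model selection needs at least 2 variants")
  spec_of <- function(v) switch(v,
    "APC" = list(effects = c("age", "period", "cohort"), fixed = character()),
    "AP" = list(effects = c("age", "period"), fixed = character()),
    "AC" = list(effects = c("age", "cohort"), fixed = character()),
    "P" = list(effects = "period", fixed = character()),
    "APC+F" = list(effects = c("age", "period", "cohort"), fixed = fixed),
    stop("unknown model variant '", v, "'"))
  rows <- lapply(seq_along(variants), function(vi) {
    sp <- spec_of(variants[vi])
    fit <- tryCatch(
      fit_apc(counts, grid, effects = sp$effects, fixed = sp$fixed,
              seed = seed + vi, check_convergence = FALSE, ...),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(variant = variants[vi], dic = NA_real_,
                        waic = NA_real_, converged = FALSE))
    data.frame(variant = variants[vi], dic = dic(fit)$dic,
               waic = waic(fit)$waic,
               converged = fit$diagnostics$converged)
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$dic))) stop("all model variants failed")
  tab$best_dic <- !is.na(tab$dic) & tab$dic == min(tab$dic, na.rm = TRUE)
  tab$best_waic <- !is.na(tab$waic) & tab$waic == min(tab$waic, na.rm = TRUE)
  tab
}
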