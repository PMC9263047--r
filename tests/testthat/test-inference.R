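test_that("posterior prevalence agrees with the conjugate beta oracle", {
  # three identical cells y = 30, N = 100 on a period-only model: the
  # posterior cell prevalence should sit at the Beta(1,1)-binomial
  # posterior mean 31/102 for a single cell, within Monte-Carlo error
  g <- small_grid()
  counts <- data.frame(i = 1L, j = 1:3, k = cohort_index(1L, 1:3, g$M, g$I),
                       y = 30, N = 100, observed = TRUE)
  class(counts) <- c("cell_counts", "data.frame")
  fit <- fit_apc(counts, g, effects = "period", n_iter = 3000, burnin = 500,
                 seed = 2)
  eta <- fit$intercept + fit$beta
  prev <- stats::plogis(eta)
  oracle <- 31 / 102  # Beta(31, 71) mean
  expect_equal(mean(prev), oracle, tolerance = 0.02)
  expect_true(all(prev > 0 & prev < 1))
})

test_that("fits are deterministic given seed and flag non-convergence", {
  g <- small_grid()
  tr <- make_truth(g, "obese", kind = "rw2",
                   sigma2 = c(age = 0.005, period = 0.005, cohort = 0.005),
                   seed = 3)
  d <- apc_design(survey_years = g$periods, n_per_wave = 1200)
  rec <- simulate_survey(tr, d, g, seed = 4)
  cc <- aggregate_cells(rec, g, "obese", strata = NULL, weighting = "crude")
  f1 <- fit_apc(cc, g, n_iter = 400, burnin = 100, seed = 7,
                check_convergence = FALSE)
  f2 <- fit_apc(cc, g, n_iter = 400, burnin = 100, seed = 7,
                check_convergence = FALSE)
  expect_identical(f1$theta, f2$theta)
  expect_identical(effect_summaries(f1), effect_summaries(f2))
  expect_false(identical(f1$theta,
                         fit_apc(cc, g, n_iter = 400, burnin = 100, seed = 8,
                                 check_convergence = FALSE)$theta))
})

test_that("every posterior draw satisfies the identifiability constraints", {
  g <- small_grid()
  tr <- make_truth(g, "obese", kind = "rw2", seed = 1)
  rec <- simulate_survey(tr, apc_design(g$periods, 800), g, seed = 2)
  cc <- aggregate_cells(rec, g, "obese", strata = NULL)
  fit <- fit_apc(cc, g, n_iter = 300, burnin = 100, seed = 3,
                 check_convergence = FALSE)
  expect_lt(max(abs(rowSums(fit$alpha))), 1e-9)
  expect_lt(max(abs(rowSums(fit$beta))), 1e-9)
  expect_lt(max(abs(rowSums(fit$gamma))), 1e-9)
  ctr <- g$locations$cohort - mean(g$locations$cohort)
  expect_lt(max(abs(fit$gamma %*% ctr)), 1e-6)
})

test_that("near-flat truth gives period effects concentrated near zero", {
  g <- apc_grid()
  tr <- make_truth(g, "obese", kind = "rw2",
                   sigma2 = c(age = 0.002, period = 0, cohort = 0), seed = 6)
  tr$fixed[] <- 0
  rec <- simulate_survey(tr, apc_design(n_per_wave = 4000), g, seed = 7)
  cc <- aggregate_cells(rec, g, "obese", strata = NULL, weighting = "crude")
  fit <- fit_apc(cc, g, n_iter = 600, burnin = 200, seed = 8,
                 check_convergence = FALSE)
  expect_true(all(abs(apply(fit$beta, 2, stats::median)) < 0.1))
})

test_that("effect summaries transform draws correctly", {
  g <- small_grid()
  n <- 200
  fk <- fake_fit(matrix(0, n, 3), y = c(1, 1, 1), N = c(2, 2, 2), grid = g)
  fk$alpha <- matrix(rep(c(0, 0.5, -0.5, 0.2), each = n), n,
                     dimnames = list(NULL, paste0("a", 1:4)))
  fk$beta <- matrix(0, n, 0); fk$gamma <- matrix(0, n, 0)
  fk$effects <- "age"
  fk$fixed <- matrix(log(0.5), n, 1, dimnames = list(NULL, "sexwoman"))
  es <- effect_summaries(fk)
  woman <- es[es$level == "sexwoman", ]
  expect_equal(woman$or, 0.5)
  expect_equal(woman$or_lower, woman$or_upper)  # degenerate interval
  a <- es[es$effect == "age", ]
  expect_equal(a$or[1], 1)          # reference level
  expect_equal(a$or[2], exp(0.5))   # OR vs reference
  expect_equal(a$median, a$lower)   # constant draws: degenerate
})

test_that("summary quantiles match a sorted-array oracle", {
  set.seed(10)
  draws <- matrix(stats::rnorm(10001), ncol = 1,
                  dimnames = list(NULL, "(Intercept)"))
  fk <- fake_fit(draws, y = 1, N = 2)
  es <- effect_summaries(fk)
  s <- sort(draws[, 1])
  # type-7 quantiles on the sorted array
  q <- function(p) {
    h <- (length(s) - 1) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1 - (h == length(s))] - s[floor(h)])
  }
  expect_equal(es$median[1], q(0.5))
  expect_equal(es$lower[1], q(0.025))
  expect_equal(es$upper[1], q(0.975))
})

test_that("DIC matches hand arithmetic and is permutation invariant", {
  y <- c(3, 7); N <- c(10, 12)
  eta <- rbind(c(-0.5, 0.2), c(-0.2, 0.4))   # two draws, two cells
  fk <- fake_fit(eta, y, N)
  out <- dic(fk)
  # hand computation with the exact binomial pmf
  devs <- apply(eta, 1, function(e) -2 * sum(stats::dbinom(y, N, stats::plogis(e), log = TRUE)))
  dbar <- mean(devs)
  dhat <- -2 * sum(stats::dbinom(y, N, stats::plogis(colMeans(eta)), log = TRUE))
  expect_equal(out$dbar, dbar, tolerance = 1e-10)
  expect_equal(out$pd, dbar - dhat, tolerance = 1e-10)
  expect_equal(out$dic, 2 * dbar - dhat, tolerance = 1e-10)
  # permutation invariance
  fk2 <- fake_fit(eta[2:1, ], y, N)
  expect_equal(dic(fk2)$dic, out$dic, tolerance = 1e-12)
  # point-mass posterior: pD = 0, DIC = D(theta-hat)
  fk3 <- fake_fit(rbind(c(-0.5, 0.2), c(-0.5, 0.2)), y, N)
  out3 <- dic(fk3)
  expect_equal(out3$pd, 0, tolerance = 1e-10)
  expect_equal(out3$dic, -2 * sum(stats::dbinom(y, N, stats::plogis(c(-0.5, 0.2)), log = TRUE)),
               tolerance = 1e-10)
})

test_that("WAIC matches an independent formula implementation", {
  set.seed(20)
  S <- 50; M <- 10
  eta <- matrix(stats::rnorm(S * M, 0, 0.7), S, M)
  y <- stats::rbinom(M, 20, 0.4); N <- rep(20, M)
  fk <- fake_fit(eta, y, N)
  out <- waic(fk)
  # independent re-implementation from the pointwise likelihood matrix
  ll <- t(vapply(seq_len(S), function(s)
    stats::dbinom(y, N, stats::plogis(eta[s, ]), log = TRUE), numeric(M)))
  lppd <- sum(log(colMeans(exp(ll))))
  p_waic <- sum(apply(ll, 2, stats::var))
  expect_equal(out$lppd, lppd, tolerance = 1e-10)
  expect_equal(out$p_waic, p_waic, tolerance = 1e-10)
  expect_equal(out$waic, -2 * (lppd - p_waic), tolerance = 1e-10)
  # point-mass posterior
  fk2 <- fake_fit(eta[c(1, 1), ], y, N)
  out2 <- waic(fk2)
  expect_equal(out2$p_waic, 0, tolerance = 1e-12)
  expect_equal(out2$waic, -2 * sum(ll[1, ]), tolerance = 1e-10)
  # an unobserved cell (N = 0) contributes nothing
  fk3 <- fake_fit(cbind(eta, 0.3), c(y, 0), c(N, 0))
  expect_equal(waic(fk3)$waic, out$waic, tolerance = 1e-12)
})

test_that("model selection tabulates all variants and prefers richer truth", {
  g <- small_grid()
  tr <- make_truth(g, "obese", kind = "rw2",
                   sigma2 = c(age = 0.05, period = 0.05, cohort = 0.05),
                   seed = 12)
  rec <- simulate_survey(tr, apc_design(g$periods, 2500), g, seed = 13)
  cc <- aggregate_cells(rec, g, "obese", strata = NULL, weighting = "crude")
  tab <- model_selection(cc, g, variants = c("APC", "P"), seed = 14,
                         n_iter = 500, burnin = 150)
  expect_equal(nrow(tab), 2)
  expect_true(any(tab$best_dic))
  expect_true(tab$dic[tab$variant == "APC"] < tab$dic[tab$variant == "P"])
  expect_error(model_selection(cc, g, variants = "APC"), "at least 2")
})
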