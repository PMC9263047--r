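# a small but real fit reused across projection tests
proj_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- apc_grid()
    tr <- make_truth(g, "obese")
    rec <- simulate_survey(tr, apc_design(n_per_wave = 2000), g, seed = 31)
    cc <- aggregate_cells(rec[rec$sex == "man", ], g, "obese", strata = NULL)
    fit <- fit_apc(cc, g, n_iter = 500, burnin = 200, seed = 32,
                   check_convergence = FALSE)
    pop <- simulate_population_projection(g, 1997:2030, growth = 0.01, seed = 33)
    cache <<- list(g = g, fit = fit, pop = pop, records = rec)
    cache
  }
})

test_that("projection covers the horizon and keeps draws coherent", {
  fx <- proj_fixture()
  years <- c(fx$g$periods, 2019:2030)
  pr <- project_prevalence(fx$fit, fx$pop, years, sex = "man", seed = 34)
  expect_equal(pr$years, sort(years))
  expect_true(all(pr$prev > 0 & pr$prev < 1))
  # cases = prevalence x population per draw
  expect_equal(pr$cases[, "2030", 3],
               pr$prev[, "2030", 3] * pr$pop["2030", 3])
  # aggregate rate equals sum(counts)/sum(pop) x 1e5 per draw (recomputed)
  t30 <- match(2030, pr$years)
  manual <- 1e5 * rowSums(pr$cases[, t30, ]) / sum(pr$pop["2030", ])
  expect_equal(unname(pr$rate[, "2030"]), manual)
  # nested quantile bands
  s <- pr$summary
  expect_true(all(s$q2.5 <= s$q25 & s$q25 <= s$median &
                    s$median <= s$q75 & s$q75 <= s$q97.5))
})

test_that("in-sample projection reproduces the fitted rates exactly", {
  fx <- proj_fixture()
  pr1 <- project_prevalence(fx$fit, fx$pop, fx$g$periods, sex = "man", seed = 1)
  pr2 <- project_prevalence(fx$fit, fx$pop, fx$g$periods, sex = "man", seed = 99)
  expect_identical(pr1$rate, pr2$rate)  # no forecast noise in-sample
  # independently recomputed from the posterior draws
  j <- match(2018, fx$g$periods)
  i <- 3
  k <- cohort_index(i, j, fx$g$M, fx$g$I)
  eta <- fx$fit$intercept + fx$fit$alpha[, i] + fx$fit$beta[, j] +
    fx$fit$gamma[, k]
  expect_equal(pr1$prev[, as.character(2018), i], stats::plogis(eta))
})

test_that("doubling the population doubles cases but not rates", {
  fx <- proj_fixture()
  pop2 <- fx$pop; pop2$population <- 2 * pop2$population
  pr1 <- project_prevalence(fx$fit, fx$pop, c(2025, 2030), sex = "man", seed = 5)
  pr2 <- project_prevalence(fx$fit, pop2, c(2025, 2030), sex = "man", seed = 5)
  expect_equal(pr2$cases, 2 * pr1$cases)
  expect_equal(pr2$rate, pr1$rate)
})

test_that("credible intervals widen with the forecast horizon", {
  fx <- proj_fixture()
  pr <- project_prevalence(fx$fit, fx$pop, c(2019, 2025, 2030), sex = "man",
                           seed = 6)
  width <- apply(pr$rate, 2, function(v) diff(stats::quantile(v, c(.025, .975))))
  expect_true(width["2019"] < width["2025"])
  expect_true(width["2025"] < width["2030"])
})

test_that("a degenerate flat posterior projects a constant prevalence", {
  g <- apc_grid()
  n <- 50
  fit <- fake_fit(matrix(0, n, 1), y = 1, N = 2, grid = g)
  fit$alpha <- matrix(0, n, g$I); fit$beta <- matrix(0, n, g$J)
  fit$gamma <- matrix(0, n, g$K)
  fit$intercept <- rep(stats::qlogis(0.3), n)
  fit$tau <- matrix(1e12, n, 3, dimnames = list(NULL, c("age", "period", "cohort")))
  fit$effects <- c("age", "period", "cohort")
  fit$counts <- structure(data.frame(i = 1, j = 1, k = 1, y = 1, N = 2),
                          outcome = "obese")
  pop <- simulate_population_projection(g, 1997:2030, growth = 0, seed = 2)
  pr <- project_prevalence(fit, pop, c(2019, 2025, 2030), sex = "man", seed = 3)
  expect_equal(max(abs(pr$prev - 0.3)), 0, tolerance = 1e-4)
})

test_that("exceedance probabilities follow their definition", {
  rate <- cbind(rep(100, 1000), rep(120, 1000))
  pr <- fake_projection(rate, c(2018, 2030), base_year = 2018)
  expect_equal(exceedance_probability(pr, 2030, margin = 0.1), 1.0)
  # symmetric difference around zero: probability ~ 1/2
  set.seed(40)
  rate2 <- cbind(100, 100 + stats::rnorm(20000))
  pr2 <- fake_projection(rate2, c(2018, 2030), 2018)
  expect_equal(exceedance_probability(pr2, 2030, margin = 0), 0.5,
               tolerance = 0.02)
  # Gaussian closed form: target ~ N(110, 5^2), base 100, m = 0.05
  set.seed(41)
  rate3 <- cbind(100, stats::rnorm(100000, 110, 5))
  pr3 <- fake_projection(rate3, c(2018, 2030), 2018)
  expect_equal(exceedance_probability(pr3, 2030, margin = 0.05),
               stats::pnorm(1), tolerance = 0.01)
  expect_error(exceedance_probability(pr3, 2031), "projected")
})

test_that("exceedance tables are complete and monotone in the margin", {
  set.seed(42)
  rate <- cbind(100, stats::rnorm(50000, 108, 12))
  pr <- fake_projection(rate, c(2018, 2030), 2018)
  tab <- exceedance_table(pr, years = 2030)
  expect_equal(nrow(tab), 6)
  expect_true(all(diff(tab$probability) <= 0))  # non-increasing in margin
  expect_true(all(tab$probability >= 0 & tab$probability <= 1))
  # m = 0 entry always >= m = 100% entry
  expect_gte(tab$probability[tab$margin == 0],
             tab$probability[tab$margin == 1])
})

test_that("age shares are conserved and respect band alignment", {
  fx <- proj_fixture()
  pr <- project_prevalence(fx$fit, fx$pop, 2030, sex = "man", seed = 8)
  sh <- age_share(pr, 2030, c(36, 65))
  expect_true(sh$share > 0 && sh$share < 1)
  # exhaustive partition sums to 1 per draw
  s1 <- age_share(pr, 2030, c(18, 35))$draws
  s2 <- age_share(pr, 2030, c(36, 65))$draws
  s3 <- age_share(pr, 2030, c(66, 100))$draws
  expect_equal(s1 + s2 + s3, rep(1, length(s1)))
  expect_error(age_share(pr, 2030, c(37, 65)), "align")
})

test_that("uniform prevalence makes the age share the population share", {
  g <- apc_grid()
  n <- 20
  fit <- fake_fit(matrix(0, n, 1), y = 1, N = 2, grid = g)
  fit$alpha <- matrix(0, n, g$I); fit$beta <- matrix(0, n, g$J)
  fit$gamma <- matrix(0, n, g$K); fit$intercept <- rep(0, n)
  fit$tau <- matrix(1e12, n, 3, dimnames = list(NULL, c("age", "period", "cohort")))
  fit$effects <- c("age", "period", "cohort")
  fit$counts <- structure(data.frame(i = 1, j = 1, k = 1, y = 1, N = 2),
                          outcome = "obese")
  pop <- simulate_population_projection(g, 2020:2030, growth = 0, seed = 9)
  pr <- project_prevalence(fit, pop, 2030, sex = "woman", seed = 10)
  sh <- age_share(pr, 2030, c(36, 65))
  pop30 <- pr$pop["2030", ]
  bands_in <- g$age_bands$lower >= 36 & g$age_bands$upper <= 65
  expect_equal(sh$share, sum(pop30[bands_in]) / sum(pop30), tolerance = 1e-4)
})

test_that("validation metrics match their definitions and hand arithmetic", {
  obs <- c(10, 12, 14, 13)
  expect_equal(validate_projection(obs, obs), list(r2 = 1, rmse = 0))
  flat <- validate_projection(obs, rep(mean(obs), 4))
  expect_equal(flat$r2, 0)
  # hand-worked 4-point series
  pred <- c(11, 11, 13, 14)
  v <- validate_projection(obs, pred)
  expect_equal(v$rmse, sqrt(mean(c(1, 1, 1, 1)^2)))
  expect_equal(v$r2, 1 - 4 / sum((obs - mean(obs))^2))
  expect_error(validate_projection(c(5, 5), c(4, 6)), "zero variance")
  expect_error(validate_projection(1:3, 1:2), "paired")
})
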