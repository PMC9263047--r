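# Shared fixtures, all built in code.

# a compact grid for brute-force checks: 4 five-year bands, 3 periods
small_grid <- function() {
  ab <- data.frame(label = c("18-22", "23-27", "28-32", "33-37"),
                   lower = c(18, 23, 28, 33), upper = c(22, 27, 32, 37))
  ab$midpoint <- (ab$lower + ab$upper) / 2
  apc_grid(age_bands = ab, periods = c(2000L, 2005L, 2010L))
}

# hand-built microdata rows (already derived)
tiny_records <- function() {
  data.frame(
    year = c(1997, 1997, 1997, 2001),
    age = c(30, 45, 60, 30),
    sex = c("man", "woman", "man", "woman"),
    education = "superior", income_q = 3, urbanisation = "rural",
    nationality = "Belgian",
    height_m = c(1.80, 1.65, 1.75, 1.70),
    weight_kg = c(100, 60, 85, 58),
    weight_survey = c(2, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

derive_flags <- function(rec) {
  fl <- bmi_flags(rec$height_m, rec$weight_kg)
  cbind(rec, fl)
}

# minimal apc_fit-shaped object for summary/IC tests: draws x cells linear
# predictors supplied directly through an identity design
fake_fit <- function(eta_draws, y, N, grid = NULL) {
  M <- ncol(eta_draws)
  counts <- data.frame(i = seq_len(M), j = 1L, k = 1L, y = y, N = N,
                       observed = N > 0)
  design <- list(X = diag(M), idx = list(intercept = 1L), p_fixed = 0L)
  structure(list(theta = eta_draws, design = design, counts = counts,
                 grid = grid, effects = character(), fixed_vars = character(),
                 n_draws = nrow(eta_draws),
                 fixed = matrix(0, nrow(eta_draws), 0),
                 intercept = eta_draws[, 1]),
            class = "apc_fit")
}

# minimal projection-result-shaped object with given per-year rate draws
fake_projection <- function(rate, years, base_year, sex = "man",
                            outcome = "obese") {
  colnames(rate) <- years
  structure(list(rate = rate, years = years, base_year = base_year,
                 sex = sex, outcome = outcome),
            class = "apc_projection")
}
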