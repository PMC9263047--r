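#' Intrinsic second-order random-walk structure on irregular locations
#'
#' Builds the rank-(n-2) structure (penalty) matrix `Q = D' W D` of an
#' intrinsic RW2 prior on strictly increasing locations. Row `i` of `D`
#' holds twice the second-order divided difference of the effect at nodes
#' `(i-1, i, i+1)` — an approximation of the second derivative that is exact
#' in annihilating constants and linears at any spacing — and `W` carries
#' trapezoidal inter-knot weights `(d[i-1] + d[i]) / 2` so the quadratic
#' form approximates the integrated squared second derivative. For unit
#' spacing `Q` reduces to the classic pentadiagonal \{1, -4, 6, -4, 1\}
#' interior stencil.
#'
#' @param locations Strictly increasing numeric vector, length >= 3.
#' @return Object of class `rw2_structure`: list with `locations`, `Q`
#'   (dense symmetric matrix), `D`, `rank` (= n - 2), and `null_basis`
#'   (n x 2 matrix spanning constants and linears in location).
#' @export
#' @examples
#' S <- rw2_structure(c(1, 2, 3))
#' S$Q   # outer product of (1, -2, 1)
rw2_structure <- function(locations) {
  n <- length(locations)
  if (n < 3) stop("RW2 structure needs at least 3 locations")
  d <- diff(locations)
  if (any(d <= 0)) stop("locations must be strictly increasing (no duplicates)")

  D <- matrix(0, n - 2, n)
  w <- numeric(n - 2)
  for (r in seq_len(n - 2)) {
    d1 <- d[r]; d2 <- d[r + 1]
    # 2 * f[x_{r}, x_{r+1}, x_{r+2}]  ~  f''(x_{r+1})
    D[r, r]     <-  2 / (d1 * (d1 + d2))
    D[r, r + 1] <- -2 / (d1 * d2)
    D[r, r + 2] <-  2 / (d2 * (d1 + d2))
    w[r] <- (d1 + d2) / 2
  }
  Q <- crossprod(D * sqrt(w))
  Q <- (Q + t(Q)) / 2
  structure(list(locations = locations, Q = Q, D = D, rank = n - 2L,
                 null_basis = cbind(constant = rep(1, n), linear = locations)),
            class = "rw2_structure")
}

#' Export a structure matrix as coordinate-format text
#'
#' Writes the non-zero entries of `S$Q` as `row col value` triplets
#' (one per line, 1-based indices) — a debugging aid for inspecting
#' penalties outside R.
#'
#' @param S An [rw2_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_matrix <- function(S, path) {
  nz <- which(abs(S$Q) > 1e-14, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  utils::write.table(data.frame(row = nz[, 1], col = nz[, 2],
                                value = S$Q[nz]),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Improper RW2 log-density
#'
#' Log-density of the intrinsic RW2 prior, up to an additive constant:
#' `((n-2)/2) log(tau) - (tau/2) x' Q x`. The exponent uses the deficient
#' rank `n - 2`, not `n`, as required for an intrinsic Gaussian Markov
#' random field.
#'
#' @param x Effect vector on the structure's locations.
#' @param tau Precision (> 0).
#' @param S An [rw2_structure()].
#' @return Scalar log-density (improper, constant omitted).
#' @export
rw2_logdensity <- function(x, tau, S) {
  if (tau <= 0) stop("tau must be positive")
  n <- length(S$locations)
  if (length(x) != n) stop("x has wrong length for this structure")
  q <- drop(crossprod(x, S$Q %*% x))
  (S$rank / 2) * log(tau) - (tau / 2) * q
}

#' Linear constraint matrix for effect identifiability
#'
#' Assembles the rows of `A` in the hard constraint `A x = 0`:
#' sum-to-zero (`"sum"`) and/or zero linear trend in location
#' (`"trend"`, with the location vector centred so the two rows are
#' orthogonal).
#'
#' @param locations Numeric locations of the effect's nodes.
#' @param type Character vector, subset of `c("sum", "trend")`.
#' @return Constraint matrix with one row per constraint.
#' @export
constraint_matrix <- function(locations, type = "sum") {
  n <- length(locations)
  rows <- list()
  if ("sum" %in% type) rows <- c(rows, list(rep(1, n)))
  if ("trend" %in% type) rows <- c(rows, list(locations - mean(locations)))
  A <- do.call(rbind, rows)
  if (qr(A)$rank < nrow(A)) stop("constraint matrix is rank deficient")
  A
}

#' Project draws onto a constraint subspace
#'
#' Orthogonal (Euclidean) projection onto \{x : A x = 0\}. The projection
#' is idempotent and never increases the RW2 quadratic penalty when the
#' constraints span directions inside the penalty's null space.
#'
#' @param x A vector, or a matrix of draws with one draw per row.
#' @param A Constraint matrix (full row rank), columns matching `x`.
#' @return Projected vector or matrix; satisfies `A x = 0` to machine
#'   precision.
#' @export
#' @examples
#' apply_constraints(c(1, 2, 3), constraint_matrix(1:3, "sum"))  # -1 0 1
apply_constraints <- function(x, A) {
  if (qr(A)$rank < nrow(A)) stop("constraint matrix is rank deficient")
  P <- t(A) %*% solve(A %*% t(A), A)
  if (is.matrix(x)) x - x %*% P else drop(x - P %*% x)
}

#' Forecast an RW2 effect beyond its observed range
#'
#' Draws future effect values from the conditional Gaussian of the future
#' nodes given the observed ones under the extended intrinsic precision
#' `tau * Q_ext`: mean `-Q_ff^{-1} Q_fo x_obs`, precision `tau * Q_ff`.
#' As `tau -> Inf` the draws collapse onto exact linear extrapolation of
#' the latest trend (for unit spacing, `x[t+1] = 2 x[t] - x[t-1]`).
#'
#' @param x_obs Effect values at the first `n_obs` locations of
#'   `S_extended`.
#' @param tau Precision of the RW2 increments (> 0).
#' @param S_extended [rw2_structure()] over observed followed by future
#'   locations.
#' @param n_draws Number of forecast draws.
#' @param seed Optional integer seed for reproducible draws.
#' @return List with `mean` (length n_future), `cov` (conditional
#'   covariance at precision `tau`), and `draws` (n_draws x n_future).
#' @export
rw2_forecast <- function(x_obs, tau, S_extended, n_draws = 1000, seed = NULL) {
  n <- length(S_extended$locations)
  n_obs <- length(x_obs)
  if (n_obs < 2) stop("RW2 forecasting needs at least 2 observed nodes")
  if (n_obs >= n) stop("extended structure has no future nodes")
  if (tau <= 0) stop("tau must be positive")
  obs <- seq_len(n_obs); fut <- (n_obs + 1L):n
  Q <- S_extended$Q
  Qff <- Q[fut, fut, drop = FALSE]
  Qfo <- Q[fut, obs, drop = FALSE]
  R <- chol(Qff)
  mu <- drop(-backsolve(R, backsolve(R, Qfo %*% x_obs, transpose = TRUE)))
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n_draws * length(fut)), n_draws)
  draws <- sweep(z %*% t(backsolve(R, diag(length(fut)))) / sqrt(tau), 2, mu, "+")
  cov <- chol2inv(R) / tau
  list(mean = mu, cov = cov, draws = draws)
}
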