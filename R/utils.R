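# internal numerical helpers

# stable binomial log-likelihood kernel on the logit scale; y may be
# non-integer (Kish-effective counts), so the combinatorial term uses
# lgamma. Cells with N = 0 contribute exactly 0.
.binom_loglik <- function(y, N, eta, include_const = TRUE) {
  ll <- y * stats::plogis(eta, log.p = TRUE) +
    (N - y) * stats::plogis(-eta, log.p = TRUE)
  if (include_const)
    ll <- ll + lgamma(N + 1) - lgamma(y + 1) - lgamma(N - y + 1)
  ll[N == 0] <- 0
  ll
}

# split-chain potential scale reduction on a single parameter trace
.split_rhat <- function(x) {
  n <- length(x)
  if (n < 8) return(NA_real_)
  half <- floor(n / 2)
  chains <- cbind(x[seq_len(half)], x[(n - half + 1):n])
  m <- ncol(chains); nn <- nrow(chains)
  mu <- colMeans(chains)
  B <- nn * stats::var(mu)
  W <- mean(apply(chains, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# crude effective sample size from the initial positive autocorrelations
.ess <- function(x) {
  n <- length(x)
  if (n < 8 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  L <- if (length(pos)) pos[1] - 1 else length(ac)
  n / (1 + 2 * sum(ac[seq_len(L)]))
}

# orthonormal basis of the orthogonal complement of the rows of A (n x n-r)
.complement_basis <- function(A) {
  n <- ncol(A)
  q <- qr(t(A))
  qr.Q(q, complete = TRUE)[, -seq_len(nrow(A)), drop = FALSE]
}
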