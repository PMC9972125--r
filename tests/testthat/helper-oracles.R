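# Independent oracles used across test files.

# Bivariate normal CDF by 1-D quadrature over the conditional CDF:
# P(Z1 <= h, Z2 <= k) = int_{-inf}^{h} dnorm(x) * pnorm((k - rho x)/sqrt(1-rho^2)) dx.
# Independent of the package's CDF backend.
pbvn_quadrature <- function(h, k, rho) {
  stats::integrate(
    function(x) stats::dnorm(x) * stats::pnorm((k - rho * x) / sqrt(1 - rho^2)),
    lower = -Inf, upper = h, rel.tol = 1e-11, abs.tol = 1e-11
  )$value
}

# Closed-form both-below orthant mass when both cuts sit at the means.
orthant_mean_cut <- function(rho) 1 / 4 + asin(rho) / (2 * pi)

# Exhaustive shortest-window HPD search (every window of m consecutive
# order statistics).
hpd_exhaustive <- function(x, level = 0.95) {
  xs <- sort(x)
  S <- length(xs)
  m <- ceiling(level * S)
  best <- c(-Inf, Inf)
  for (i in 1:(S - m + 1)) {
    if (xs[i + m - 1] - xs[i] < best[2] - best[1]) {
      best <- c(xs[i], xs[i + m - 1])
    }
  }
  best
}

# Unnormalized log posterior of the data-augmented linear factor model,
# for grid checks of the Gibbs full conditionals.
log_post_lfm <- function(X, eta, tau, lambda, psi, prior) {
  N <- nrow(X); J <- ncol(X)
  mu <- rep(tau, each = N) + outer(eta, lambda)
  ll <- sum(stats::dnorm(X, mu, rep(sqrt(psi), each = N), log = TRUE))
  lp_eta <- sum(stats::dnorm(eta, 0, 1, log = TRUE))
  lp_tau <- sum(stats::dnorm(tau, prior$tau_mean, prior$tau_sd, log = TRUE))
  lp_lam <- sum(stats::dnorm(lambda, prior$lambda_mean, prior$lambda_sd, log = TRUE))
  lp_psi <- sum(prior$psi_shape * log(prior$psi_scale) - lgamma(prior$psi_shape) -
                  (prior$psi_shape + 1) * log(psi) - prior$psi_scale / psi)
  ll + lp_eta + lp_tau + lp_lam + lp_psi
}

# Normalize exp(logp) evaluated on an equally spaced grid to a density.
grid_density <- function(logp, grid) {
  p <- exp(logp - max(logp))
  p / (sum(p) * (grid[2] - grid[1]))
}
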