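#' Maximum-likelihood fit of the unidimensional linear factor model
#'
#' Fits \eqn{X_{ij} = \tau_j + \lambda_j \eta_i + \epsilon_{ij}} under the
#' identification \eqn{\kappa = 0, \Phi = 1}. Intercepts are the item means
#' (their ML estimates when unconstrained); loadings and residual variances
#' minimize the normal-theory discrepancy
#' \deqn{F(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1})
#'       - \log|S| - J, \qquad \Sigma(\theta) = \lambda\lambda' + \mathrm{diag}(\psi),}
#' with \eqn{S} the ML (divisor \eqn{N}) sample covariance. Residual
#' variances are optimized on the log scale, so every returned solution is
#' admissible (\eqn{\psi_j > 0}) — Heywood cases are excluded by
#' construction, which keeps downstream index computations defined for every
#' bootstrap refit. If the summed loading estimate is negative the sign of
#' all loadings is flipped (the identification leaves it free; positive
#' keying is the convention here).
#'
#' Start values come from the leading eigenpair of `S`; optimization is
#' box-constrained quasi-Newton (L-BFGS-B) with analytic gradients, with
#' each `log(psi_j)` floored at 0.5% of the observed item variance so that
#' Heywood-type boundary solutions remain admissible and usable downstream.
#' A fit is `converged` only if the final projected gradient of `F`
#' vanishes to within `grad_tol` (interior coordinates at most `grad_tol`
#' in norm; floored coordinates pushing outward).
#'
#' @param data Data frame or numeric matrix of item responses (rows =
#'   respondents, no missing values).
#' @param grad_tol Gradient-norm convergence tolerance. Default `1e-6`.
#' @param max_iter Maximum BFGS iterations. Default 500.
#' @param start Optional list with numeric vectors `loadings` and
#'   `residual_variances` overriding the default start values.
#' @return An object of class `lfm_fit`: list with `params` (an
#'   [lfm_params]), `loglik` (raw-data Gaussian log-likelihood at the
#'   optimum), `discrepancy` (minimized F), `converged`, `iterations`,
#'   `n_obs`, `sample_cov`.
#' @examples
#' X <- sim_responses(sim_params(0.6, 5, seed = 1), n = 300, seed = 2)
#' fit <- fit_lfm(X)
#' glance(fit)
#' @export
fit_lfm <- function(data, grad_tol = 1e-6, max_iter = 500, start = NULL) {
  X <- response_matrix(data)
  N <- nrow(X)
  J <- ncol(X)
  if (N <= J) abort("need more respondents than items to fit the model")

  tau <- unname(colMeans(X))
  S <- crossprod(sweep(X, 2, tau)) / N
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= max(ev$values) * 1e-10) {
    abort("sample covariance matrix is singular (collinear or constant items); cannot fit")
  }
  log_det_S <- sum(log(ev$values))

  if (is.null(start)) {
    lam0 <- ev$vectors[, 1] * sqrt(ev$values[1])
    if (sum(lam0) < 0) lam0 <- -lam0
    psi0 <- pmax(diag(S) - lam0^2, 0.05 * diag(S))
  } else {
    lam0 <- start$loadings
    psi0 <- start$residual_variances
  }

  # theta = (lambda, log psi); F and its gradient.
  obj <- function(theta) {
    lam <- theta[1:J]
    psi <- exp(theta[(J + 1):(2 * J)])
    sig_inv <- woodbury_inv(lam, psi)
    ld <- log(1 + sum(lam^2 / psi)) + sum(log(psi))
    ld + sum(sig_inv * S) - log_det_S - J
  }
  grad <- function(theta) {
    lam <- theta[1:J]
    psi <- exp(theta[(J + 1):(2 * J)])
    sig_inv <- woodbury_inv(lam, psi)
    A <- sig_inv - sig_inv %*% S %*% sig_inv
    c(2 * as.numeric(A %*% lam), diag(A) * psi)
  }

  # Heywood-prone resamples push psi_j to 0, where the log-scale gradient
  # flattens and an unconstrained optimizer can never formally converge; a
  # small floor (0.5% of the observed item variance) keeps the solution
  # admissible and convergence decidable at the bound (KKT: the projected
  # gradient must not point back inside).
  lower <- c(rep(-Inf, J), log(0.005 * diag(S)))
  opt <- optim(pmax(c(lam0, log(psi0)), lower + 1e-8), obj, grad,
               method = "L-BFGS-B", lower = lower,
               control = list(maxit = max_iter, factr = 10))
  g <- grad(opt$par)
  at_bound <- opt$par <= lower + 1e-7
  converged <- sqrt(sum(g[!at_bound]^2)) <= grad_tol &&
    all(g[at_bound] >= -grad_tol)
  lam <- opt$par[1:J]
  if (sum(lam) < 0) lam <- -lam
  psi <- exp(opt$par[(J + 1):(2 * J)])

  params <- lfm_params(loadings = lam, intercepts = tau,
                       residual_variances = psi)
  sigma <- tcrossprod(lam) + diag(psi, J)
  loglik <- -N / 2 * (J * log(2 * pi) + determinant(sigma)$modulus[1] +
                        sum(solve(sigma) * S))

  structure(
    list(params = params, loglik = loglik, discrepancy = opt$value,
         converged = converged, iterations = opt$counts[["function"]],
         n_obs = N, sample_cov = S),
    class = "lfm_fit"
  )
}

# (diag(psi) + lam lam')^{-1} via Sherman-Morrison.
woodbury_inv <- function(lam, psi) {
  u <- lam / psi
  diag(1 / psi, length(psi)) - tcrossprod(u) / (1 + sum(lam * u))
}

#' @export
print.lfm_fit <- function(x, ...) {
  cat(sprintf(
    "<lfm_fit> %d items, N = %d; logLik %.2f; %s\n",
    n_items(x$params), x$n_obs, x$loglik,
    if (x$converged) "converged" else "DID NOT CONVERGE"
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a fitted linear factor model
#'
#' @param x An `lfm_fit` object.
#' @param ... Unused.
#' @return One row per item: `item`, `loading`, `intercept`,
#'   `residual_variance`.
#' @export
tidy.lfm_fit <- function(x, ...) tidy(x$params)

#' One-row model summary of a fitted linear factor model
#'
#' Includes the implied summed-score moments and reliability alongside fit
#' information.
#'
#' @param x An `lfm_fit` object.
#' @param ... Unused.
#' @export
glance.lfm_fit <- function(x, ...) {
  m <- implied_moments(x$params)
  tibble(
    n_obs = x$n_obs, n_items = n_items(x$params),
    loglik = x$loglik, discrepancy = x$discrepancy,
    converged = x$converged,
    mu_sum = m$mu_sum, var_sum = m$var_sum, rho = m$rho, omega = m$omega
  )
}
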