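#' Model-implied moments of the summed score
#'
#' Maps item parameters to the implied mean and variance of the summed score
#' \eqn{X^* = \sum_j X_{ij}}, its correlation with the latent trait, and
#' coefficient omega. With \eqn{\tau^* = \sum_j \tau_j},
#' \eqn{\lambda^* = \sum_j \lambda_j}, \eqn{\psi^* = \sum_j \psi_j}:
#' \deqn{\mu_{X^*} = \tau^* + \lambda^* \kappa, \qquad
#'       \sigma^2_{X^*} = \lambda^{*2} \Phi + \psi^*,}
#' \deqn{\rho = \mathrm{Cor}(X^*, \eta)
#'       = \lambda^* \Phi^{1/2} / (\lambda^{*2}\Phi + \psi^*)^{1/2}, \qquad
#'       \omega = \lambda^{*2}\Phi / (\lambda^{*2}\Phi + \psi^*).}
#' Omega is the correlation between the summed scores of two parallel
#' administrations and equals \eqn{\rho^2} identically.
#'
#' @param params An [lfm_params] object (or an `lfm_fit`, whose estimates
#'   are used).
#' @return A one-row tibble with columns `tau_star`, `lambda_star`,
#'   `psi_star`, `mu_sum`, `var_sum`, `rho`, `omega`, `latent_mean`,
#'   `latent_variance`.
#' @examples
#' implied_moments(lfm_params(rep(0.6, 5), intercepts = 3))
#' @export
implied_moments <- function(params) {
  params <- as_lfm_params(params)
  kappa <- params$latent_mean
  phi <- params$latent_variance
  tau_star <- sum(params$intercepts)
  lambda_star <- sum(params$loadings)
  psi_star <- sum(params$residual_variances)
  var_sum <- lambda_star^2 * phi + psi_star
  if (var_sum <= 0) abort("degenerate model: implied summed-score variance is not positive")
  tibble(
    tau_star = tau_star,
    lambda_star = lambda_star,
    psi_star = psi_star,
    mu_sum = tau_star + lambda_star * kappa,
    var_sum = var_sum,
    rho = lambda_star * sqrt(phi) / sqrt(var_sum),
    omega = lambda_star^2 * phi / var_sum,
    latent_mean = kappa,
    latent_variance = phi
  )
}
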