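#' Draw a generating parameter set for a simulation condition
#'
#' Loadings are drawn i.i.d. from `Uniform(loading - 0.2, loading + 0.2)`,
#' intercepts are 0, and each residual variance is set to
#' \eqn{1 - \lambda_j^2} so every indicator has total variance exactly 1
#' under the standard-normal latent trait. This is the generating model of
#' the coverage study: condition-level truth is one such draw, held fixed
#' across replications.
#'
#' @param loading Target mean loading, in (0.2, 0.8) so that the uniform
#'   limits keep every residual variance positive.
#' @param n_items Number of items J >= 2.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return An [lfm_params] object with `latent_mean = 0`,
#'   `latent_variance = 1`.
#' @examples
#' sim_params(loading = 0.5, n_items = 5, seed = 1)
#' @export
sim_params <- function(loading, n_items, seed = NULL) {
  if (loading <= 0.2 || loading >= 0.8) {
    abort("`loading` must lie in (0.2, 0.8): uniform limits at +/- 0.2 would otherwise allow loading^2 >= 1")
  }
  if (n_items < 2) abort("`n_items` must be at least 2")
  lam <- with_seed_maybe(seed, runif(n_items, loading - 0.2, loading + 0.2))
  lfm_params(loadings = lam, intercepts = 0, residual_variances = 1 - lam^2)
}

#' Simulate item responses from a linear factor model
#'
#' Generates `n` respondents: latent scores
#' \eqn{\eta_i \sim N(\kappa, \Phi)}, then
#' \eqn{X_{ij} = \tau_j + \lambda_j \eta_i + \epsilon_{ij}} with
#' \eqn{\epsilon_{ij} \sim N(0, \psi_j)}.
#'
#' @param params An [lfm_params] object.
#' @param n Number of respondents.
#' @param seed Optional integer seed.
#' @param item_names Column names; default `item_1 ... item_J`.
#' @return A tibble with `n` rows and one numeric column per item.
#' @examples
#' sim_responses(sim_params(0.5, 5, seed = 1), n = 10, seed = 2)
#' @export
sim_responses <- function(params, n, seed = NULL, item_names = NULL) {
  params <- as_lfm_params(params)
  if (n < 1) abort("`n` must be at least 1")
  J <- n_items(params)
  if (is.null(item_names)) item_names <- paste0("item_", seq_len(J))
  X <- with_seed_maybe(seed, {
    eta <- rnorm(n, params$latent_mean, sqrt(params$latent_variance))
    eps <- matrix(rnorm(n * J, 0, rep(sqrt(params$residual_variances), each = n)),
                  nrow = n, ncol = J)
    rep(params$intercepts, each = n) + outer(eta, params$loadings) + eps
  })
  colnames(X) <- item_names
  as_tibble(X)
}

# Coerce a data frame (or matrix) of item responses to a numeric matrix,
# validating completeness.
response_matrix <- function(data) {
  if (is.data.frame(data)) {
    ok <- vapply(data, is.numeric, logical(1))
    if (!all(ok)) {
      abort(paste0("non-numeric item columns: ",
                   paste(names(data)[!ok], collapse = ", ")))
    }
    data <- as.matrix(data)
  }
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a data frame or numeric matrix of item responses")
  }
  if (anyNA(data)) abort("missing item responses are not supported")
  if (ncol(data) < 2) abort("at least two items are required")
  if (is.null(colnames(data))) colnames(data) <- paste0("item_", seq_len(ncol(data)))
  data
}
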