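#' Parameters of a unidimensional linear factor model
#'
#' Bundles the item parameters of the model
#' \deqn{X_{ij} = \tau_j + \lambda_j \eta_i + \epsilon_{ij}, \qquad
#'       \eta_i \sim N(\kappa, \Phi), \quad
#'       \epsilon_{ij} \sim N(0, \psi_j),}
#' where \eqn{\tau_j} is the intercept, \eqn{\lambda_j} the loading and
#' \eqn{\psi_j} the residual variance of item \eqn{j}. The latent mean
#' \eqn{\kappa} and variance \eqn{\Phi} default to the usual identification
#' (0 and 1) but are carried symbolically so implied moments stay correct
#' under other identifications.
#'
#' @param loadings Numeric vector of factor loadings (length J >= 2).
#' @param intercepts Item intercepts; a scalar is recycled. Default 0.
#' @param residual_variances Positive residual variances; a scalar is
#'   recycled. Default `1 - loadings^2` (unit total indicator variance),
#'   which requires `|loadings| < 1`.
#' @param latent_mean,latent_variance Mean and variance of the latent trait.
#' @return An object of class `lfm_params`: a list with elements `loadings`,
#'   `intercepts`, `residual_variances`, `latent_mean`, `latent_variance`.
#' @examples
#' lfm_params(loadings = rep(0.6, 5), intercepts = 3)
#' @export
lfm_params <- function(loadings, intercepts = 0, residual_variances = NULL,
                       latent_mean = 0, latent_variance = 1) {
  loadings <- as.numeric(loadings)
  J <- length(loadings)
  if (J < 2) abort("at least two items are required")
  if (is.null(residual_variances)) {
    if (any(loadings^2 >= 1)) {
      abort("default residual variances 1 - loading^2 require |loading| < 1")
    }
    residual_variances <- 1 - loadings^2
  }
  intercepts <- rep_len(as.numeric(intercepts), J)
  residual_variances <- rep_len(as.numeric(residual_variances), J)
  if (any(residual_variances <= 0)) abort("residual variances must be > 0")
  if (latent_variance <= 0) abort("latent variance must be > 0")
  structure(
    list(
      loadings = loadings,
      intercepts = intercepts,
      residual_variances = residual_variances,
      latent_mean = as.numeric(latent_mean),
      latent_variance = as.numeric(latent_variance)
    ),
    class = "lfm_params"
  )
}

#' @export
print.lfm_params <- function(x, ...) {
  cat(sprintf(
    "<lfm_params> %d items; latent mean %.3g, variance %.3g\n",
    length(x$loadings), x$latent_mean, x$latent_variance
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn lfm_params `tidy()` returns one row per item with columns
#'   `item`, `loading`, `intercept`, `residual_variance`.
#' @param x An `lfm_params` object.
#' @param ... Unused.
#' @export
tidy.lfm_params <- function(x, ...) {
  tibble(
    item = seq_along(x$loadings),
    loading = x$loadings,
    intercept = x$intercepts,
    residual_variance = x$residual_variances
  )
}

n_items <- function(params) length(params$loadings)

as_lfm_params <- function(x) {
  if (inherits(x, "lfm_params")) return(x)
  if (inherits(x, "lfm_fit")) return(x$params)
  abort("expected an `lfm_params` or `lfm_fit` object")
}
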