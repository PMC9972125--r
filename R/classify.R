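#' Specify decision cutpoints
#'
#' A decision rule needs a cutpoint on the latent trait (the gold standard)
#' and one on the summed score. Either can be given on its own scale
#' (`eta_cut`, `sum_cut`), or both can be derived from a shared standardized
#' offset `cut_sd`, resolved against implied moments as
#' \eqn{\kappa + c\sqrt{\Phi}} and \eqn{\mu_{X^*} + c\,\sigma_{X^*}}.
#' `direction` states which side of the cut is the "positive" (flagged)
#' decision, applied identically to both axes: `"above"` flags scores above
#' the cut, `"below"` flags scores at or below it (e.g. screening for *low*
#' levels of a trait).
#'
#' @param cut_sd Standardized offset shared by both axes; used for any cut
#'   not given explicitly.
#' @param eta_cut Cutpoint on the latent-trait scale.
#' @param sum_cut Cutpoint on the raw summed-score scale.
#' @param direction `"above"` or `"below"`.
#' @return A `cutpoint_spec` object.
#' @examples
#' cutpoints(cut_sd = 0)                      # both cuts at the mean
#' cutpoints(eta_cut = -1, sum_cut = 53, direction = "below")
#' @export
cutpoints <- function(cut_sd = NULL, eta_cut = NULL, sum_cut = NULL,
                      direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (is.null(cut_sd) && (is.null(eta_cut) || is.null(sum_cut))) {
    abort("supply `cut_sd`, or both `eta_cut` and `sum_cut`")
  }
  structure(
    list(cut_sd = cut_sd, eta_cut = eta_cut, sum_cut = sum_cut,
         direction = direction),
    class = "cutpoint_spec"
  )
}

#' @export
print.cutpoint_spec <- function(x, ...) {
  cat("<cutpoint_spec>",
      if (!is.null(x$cut_sd)) sprintf("cut_sd = %g;", x$cut_sd),
      if (!is.null(x$eta_cut)) sprintf("eta_cut = %g;", x$eta_cut),
      if (!is.null(x$sum_cut)) sprintf("sum_cut = %g;", x$sum_cut),
      sprintf("positive = %s cut\n", x$direction))
  invisible(x)
}

#' Resolve a cutpoint specification against implied moments
#'
#' Explicit raw cuts are kept; cuts given as a standardized offset are
#' translated to the raw scales of the supplied moments.
#'
#' @param cut A [cutpoints] specification.
#' @param moments A one-row tibble from [implied_moments()].
#' @return A `cutpoint_spec` with both `eta_cut` and `sum_cut` filled in.
#' @export
resolve_cutpoints <- function(cut, moments) {
  stopifnot(inherits(cut, "cutpoint_spec"))
  out <- cut
  if (is.null(out$eta_cut)) {
    out$eta_cut <- moments$latent_mean + cut$cut_sd * sqrt(moments$latent_variance)
  }
  if (is.null(out$sum_cut)) {
    out$sum_cut <- moments$mu_sum + cut$cut_sd * sqrt(moments$var_sum)
  }
  out
}

# Standard bivariate normal CDF P(Z1 <= h, Z2 <= k) at correlation rho,
# vectorized over all three arguments. Deterministic double-precision
# algorithm (TVPACK); absolute error far below the 1e-8 contract.
pbvn <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(h, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (abs(rho[i]) >= 1) abort("|correlation| must be < 1; the bivariate distribution is degenerate (perturb the model, e.g. a small residual variance)")
    out[i] <- if (rho[i] == 0) {
      pnorm(h[i]) * pnorm(k[i])
    } else {
      mvtnorm::pmvnorm(
        upper = c(h[i], k[i]),
        corr = matrix(c(1, rho[i], rho[i], 1), 2),
        algorithm = mvtnorm::TVPACK(1e-12)
      )[1]
    }
  }
  out
}

# Quadrant masses of a standard bivariate normal cut at (zx, ze), labelled
# relative to the positive direction. Derived from one CDF call plus two
# univariate CDFs so the four masses sum to 1 up to CDF error. Vectorized.
quadrant_core <- function(zx, ze, rho, direction) {
  ll <- pbvn(zx, ze, rho)            # below both cuts
  px <- pnorm(zx)
  pe <- pnorm(ze)
  lh <- px - ll                      # below on x, above on eta
  hl <- pe - ll                      # above on x, below on eta
  hh <- 1 - px - pe + ll             # above both cuts
  if (direction == "above") {
    tibble(both_negative = ll, neg_pos = lh, pos_neg = hl, both_positive = hh)
  } else {
    tibble(both_negative = hh, neg_pos = hl, pos_neg = lh, both_positive = ll)
  }
}

standardized_cuts <- function(moments, cut) {
  cut <- resolve_cutpoints(cut, moments)
  list(
    zx = (cut$sum_cut - moments$mu_sum) / sqrt(moments$var_sum),
    ze = (cut$eta_cut - moments$latent_mean) / sqrt(moments$latent_variance),
    direction = cut$direction
  )
}

#' Quadrant probabilities for classification accuracy
#'
#' Cuts the bivariate normal distribution of the summed score and the latent
#' trait (correlation \eqn{\rho = \mathrm{Cor}(X^*, \eta)}) at the resolved
#' cutpoints, and integrates the four quadrants. `both_negative` and
#' `both_positive` are the correct classifications (true negative / true
#' positive); `neg_pos` is a summed-score negative for a latent positive (a
#' false negative), `pos_neg` the reverse.
#'
#' @param moments A one-row tibble from [implied_moments()], or an
#'   [lfm_params]/`lfm_fit` object.
#' @param cut A [cutpoints] specification.
#' @return A one-row tibble with columns `both_negative`, `neg_pos`,
#'   `pos_neg`, `both_positive`, summing to 1.
#' @examples
#' accuracy_quadrants(lfm_params(rep(0.6, 5)), cutpoints(cut_sd = 0))
#' @export
accuracy_quadrants <- function(moments, cut) {
  moments <- as_moments(moments)
  z <- standardized_cuts(moments, cut)
  quadrant_core(z$zx, z$ze, moments$rho, z$direction)
}

#' Quadrant probabilities for classification consistency
#'
#' Cuts the bivariate normal distribution of the summed scores of two
#' parallel administrations: both margins have mean \eqn{\mu_{X^*}} and
#' variance \eqn{\sigma^2_{X^*}}, correlation \eqn{\omega}, and both axes
#' share the summed-score cutpoint. `both_negative`/`both_positive` are the
#' consistent decisions.
#'
#' @inheritParams accuracy_quadrants
#' @return A one-row tibble as in [accuracy_quadrants()].
#' @examples
#' consistency_quadrants(lfm_params(rep(0.6, 5)), cutpoints(cut_sd = 0))
#' @export
consistency_quadrants <- function(moments, cut) {
  moments <- as_moments(moments)
  z <- standardized_cuts(moments, cut)
  quadrant_core(z$zx, z$zx, moments$omega, z$direction)
}

as_moments <- function(x) {
  if (is.data.frame(x) && all(c("mu_sum", "var_sum", "rho", "omega") %in% names(x))) {
    return(x)
  }
  implied_moments(as_lfm_params(x))
}

#' Classification accuracy indices from quadrant probabilities
#'
#' @param quadrants A tibble from [accuracy_quadrants()].
#' @return A one-row tibble with `rate` (probability of a correct
#'   classification), `sensitivity` (correct among latent positives) and
#'   `specificity` (correct among latent negatives).
#' @examples
#' ca_indices(accuracy_quadrants(lfm_params(rep(0.6, 5)), cutpoints(cut_sd = 0)))
#' @export
ca_indices <- function(quadrants) {
  a <- quadrants$both_negative; b <- quadrants$neg_pos
  c_ <- quadrants$pos_neg; d <- quadrants$both_positive
  if (any(b + d <= 0)) abort("no mass on the condition-positive margin (B + D = 0); sensitivity undefined")
  if (any(a + c_ <= 0)) abort("no mass on the condition-negative margin (A + C = 0); specificity undefined")
  tibble(
    rate = (a + d) / (a + b + c_ + d),
    sensitivity = d / (b + d),
    specificity = a / (a + c_)
  )
}

#' Classification consistency from quadrant probabilities
#'
#' @param quadrants A tibble from [consistency_quadrants()].
#' @return The probability of the same decision on both administrations.
#' @examples
#' cc_index(consistency_quadrants(lfm_params(rep(0.6, 5)), cutpoints(cut_sd = 0)))
#' @export
cc_index <- function(quadrants) {
  with(quadrants,
       (both_negative + both_positive) /
         (both_negative + neg_pos + pos_neg + both_positive))
}

#' Classification accuracy and consistency indices of a factor model
#'
#' The single entry point composed by the bootstrap and the posterior
#' propagation: implied moments, both cut bivariate normal distributions,
#' and the four indices.
#'
#' @param params An [lfm_params] object or an `lfm_fit`.
#' @param cut A [cutpoints] specification.
#' @return A one-row tibble with columns `rate`, `sensitivity`,
#'   `specificity`, `consistency`.
#' @examples
#' classification_indices(lfm_params(rep(0.6, 5), intercepts = 3),
#'                        cutpoints(cut_sd = 0))
#' @export
classification_indices <- function(params, cut) {
  m <- as_moments(params)
  ca <- ca_indices(accuracy_quadrants(m, cut))
  ca$consistency <- cc_index(consistency_quadrants(m, cut))
  ca
}

# Vectorized index computation from summed-score parameter vectors; the hot
# path under bootstrap resamples and posterior draws. The cutpoint spec must
# already be resolved to raw cuts.
indices_core <- function(tau_star, lambda_star, psi_star, kappa, phi, cut) {
  var_sum <- lambda_star^2 * phi + psi_star
  mu_sum <- tau_star + lambda_star * kappa
  rho <- lambda_star * sqrt(phi) / sqrt(var_sum)
  omega <- rho^2
  zx <- (cut$sum_cut - mu_sum) / sqrt(var_sum)
  ze <- (cut$eta_cut - kappa) / sqrt(phi)
  acc <- quadrant_core(zx, ze, rho, cut$direction)
  con <- quadrant_core(zx, zx, omega, cut$direction)
  out <- ca_indices(acc)
  out$consistency <- cc_index(con)
  out
}
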