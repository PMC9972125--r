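#' Percentile-bootstrap distribution of the classification indices
#'
#' Propagates factor-model sampling uncertainty into the indices by the
#' resample–refit–recompute recipe: respondents (rows) are resampled with
#' replacement, the factor model is refit by [fit_lfm()] on each resample,
#' and the four indices are recomputed from each refit via
#' [classification_indices()]. The pooled draws are the empirical
#' distributions from which percentile confidence intervals are read off by
#' [summarize_draws()].
#'
#' When the cutpoints are given as a standardized offset (`cut_sd`), they
#' are resolved once against the full-sample fit and held fixed across
#' resamples, mirroring a fixed decision rule; set `refit_cut = TRUE` to
#' re-resolve them inside every resample instead (a sensitivity analysis).
#'
#' Resamples whose refit does not converge are discarded and redrawn (never
#' silently kept), up to `10 * resamples` total attempts; the discard count
#' is recorded on the result. If failures exceed 10% of the requested
#' resamples the model is too unstable for percentile intervals and the run
#' aborts.
#'
#' @param data Data frame or matrix of item responses.
#' @param cut A [cutpoints] specification.
#' @param resamples Number of bootstrap resamples B. Default 500.
#' @param seed Optional integer seed; resamples use independently spawned
#'   child seeds, so results are identical under any execution order.
#' @param refit_cut Re-resolve `cut_sd` cutpoints within each resample?
#'   Default `FALSE`.
#' @return An `index_draws` tibble with `resamples` rows and columns `draw`,
#'   `rate`, `sensitivity`, `specificity`, `consistency`; attributes
#'   `source = "bootstrap"` and `n_failed`.
#' @examples
#' X <- sim_responses(sim_params(0.5, 5, seed = 1), n = 200, seed = 2)
#' bootstrap_indices(X, cutpoints(cut_sd = 0), resamples = 25, seed = 3)
#' @export
bootstrap_indices <- function(data, cut, resamples = 500, seed = NULL,
                              refit_cut = FALSE) {
  X <- response_matrix(data)
  stopifnot(inherits(cut, "cutpoint_spec"), resamples >= 1)
  N <- nrow(X)

  base_fit <- fit_lfm(X)
  if (!base_fit$converged) {
    abort("the full-sample maximum-likelihood fit did not converge")
  }
  fixed_cut <- resolve_cutpoints(cut, implied_moments(base_fit$params))

  max_attempts <- 10L * resamples
  seeds <- if (is.null(seed)) {
    sample.int(2147483646L, max_attempts)
  } else {
    spawn_seeds(seed, max_attempts)
  }

  tau_star <- lambda_star <- psi_star <- numeric(resamples)
  per_resample <- if (refit_cut) vector("list", resamples) else NULL
  n_failed <- 0L
  kept <- 0L
  attempt <- 0L
  while (kept < resamples && attempt < max_attempts) {
    attempt <- attempt + 1L
    idx <- withr::with_seed(seeds[attempt], sample.int(N, N, replace = TRUE))
    fit <- tryCatch(fit_lfm(X[idx, , drop = FALSE]), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      if (n_failed > 0.1 * resamples) {
        abort(sprintf(
          "bootstrap aborted: %d of %d refits failed; the model is too unstable for percentile intervals",
          n_failed, attempt
        ))
      }
      next
    }
    kept <- kept + 1L
    p <- fit$params
    tau_star[kept] <- sum(p$intercepts)
    lambda_star[kept] <- sum(p$loadings)
    psi_star[kept] <- sum(p$residual_variances)
    if (refit_cut) {
      per_resample[[kept]] <- classification_indices(p, cut)
    }
  }
  if (kept < resamples) {
    abort("bootstrap aborted: attempt budget exhausted before reaching the requested number of resamples")
  }

  draws <- if (refit_cut) {
    dplyr::bind_rows(per_resample)
  } else {
    indices_core(tau_star, lambda_star, psi_star,
                 kappa = 0, phi = 1, cut = fixed_cut)
  }
  new_index_draws(
    dplyr::bind_cols(tibble(draw = seq_len(resamples)), draws),
    source = "bootstrap", n_failed = n_failed, cut = fixed_cut
  )
}
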