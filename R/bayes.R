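#' Prior specifications for the Bayesian linear factor model
#'
#' `prior_diffuse()` builds the wide priors used as the vague default:
#' \eqn{\tau_j \sim N(3, \mathrm{sd}\,10)}, \eqn{\lambda_j \sim N(1,
#' \mathrm{sd}\,10)}, \eqn{\psi_j \sim \mathrm{IG}(5, 10)} (shape, scale).
#' The normal spread arguments are standard deviations throughout, and the
#' inverse-gamma scale is the rate of the reciprocal gamma.
#'
#' `prior_empirical()` builds empirical, weakly informative priors from a
#' converged maximum-likelihood fit: normals centered at the ML estimates
#' with standard deviation 1 for loadings and intercepts, and for each
#' residual variance an inverse gamma carrying a pseudo sample size
#' \eqn{n_0}: shape \eqn{n_0/2}, scale \eqn{(n_0/2)\,\hat\psi_j} (prior mean
#' \eqn{\hat\psi_j n_0/(n_0 - 2)}). The added spread deliberately exceeds
#' the ML standard errors.
#'
#' @param n_items Number of items J.
#' @return An `lfm_prior` object: per-item vectors `tau_mean`, `tau_sd`,
#'   `lambda_mean`, `lambda_sd`, `psi_shape`, `psi_scale`, plus a `label`.
#' @examples
#' prior_diffuse(5)
#' @export
prior_diffuse <- function(n_items) {
  new_lfm_prior(
    tau_mean = rep(3, n_items), tau_sd = rep(10, n_items),
    lambda_mean = rep(1, n_items), lambda_sd = rep(10, n_items),
    psi_shape = rep(5, n_items), psi_scale = rep(10, n_items),
    label = "diffuse"
  )
}

#' @rdname prior_diffuse
#' @param fit A converged `lfm_fit`.
#' @param pseudo_n Pseudo sample size encoded in the residual-variance
#'   prior. Default 20.
#' @examples
#' X <- sim_responses(sim_params(0.6, 5, seed = 1), n = 300, seed = 2)
#' prior_empirical(fit_lfm(X))
#' @export
prior_empirical <- function(fit, pseudo_n = 20) {
  stopifnot(inherits(fit, "lfm_fit"))
  if (!fit$converged) {
    abort("empirical priors require a converged maximum-likelihood fit")
  }
  p <- fit$params
  J <- n_items(p)
  new_lfm_prior(
    tau_mean = p$intercepts, tau_sd = rep(1, J),
    lambda_mean = p$loadings, lambda_sd = rep(1, J),
    psi_shape = rep(pseudo_n / 2, J),
    psi_scale = (pseudo_n / 2) * p$residual_variances,
    label = "empirical_weak"
  )
}

#' @rdname prior_diffuse
#' @param tau_mean,tau_sd,lambda_mean,lambda_sd Per-item normal prior
#'   moments (scalars recycled).
#' @param psi_shape,psi_scale Per-item inverse-gamma shape and scale.
#' @param label Prior family label.
#' @export
lfm_prior <- function(tau_mean, tau_sd, lambda_mean, lambda_sd,
                      psi_shape, psi_scale, label = "custom") {
  J <- max(lengths(list(tau_mean, tau_sd, lambda_mean, lambda_sd,
                        psi_shape, psi_scale)))
  new_lfm_prior(
    rep_len(tau_mean, J), rep_len(tau_sd, J),
    rep_len(lambda_mean, J), rep_len(lambda_sd, J),
    rep_len(psi_shape, J), rep_len(psi_scale, J), label
  )
}

new_lfm_prior <- function(tau_mean, tau_sd, lambda_mean, lambda_sd,
                          psi_shape, psi_scale, label) {
  if (any(tau_sd <= 0) || any(lambda_sd <= 0)) abort("prior standard deviations must be > 0")
  if (any(psi_shape <= 0) || any(psi_scale <= 0)) abort("inverse-gamma shape and scale must be > 0")
  structure(
    list(tau_mean = as.numeric(tau_mean), tau_sd = as.numeric(tau_sd),
         lambda_mean = as.numeric(lambda_mean), lambda_sd = as.numeric(lambda_sd),
         psi_shape = as.numeric(psi_shape), psi_scale = as.numeric(psi_scale),
         label = label),
    class = "lfm_prior"
  )
}

#' @export
print.lfm_prior <- function(x, ...) {
  cat(sprintf("<lfm_prior> %s, %d items\n", x$label, length(x$tau_mean)))
  print(tibble(
    item = seq_along(x$tau_mean),
    tau_mean = x$tau_mean, tau_sd = x$tau_sd,
    lambda_mean = x$lambda_mean, lambda_sd = x$lambda_sd,
    psi_shape = x$psi_shape, psi_scale = x$psi_scale
  ), ...)
  invisible(x)
}

#' Gibbs sampler for the Bayesian unidimensional linear factor model
#'
#' Data-augmented conjugate Gibbs sampling with \eqn{\kappa = 0} and
#' \eqn{\Phi = 1} fixed for identification. Each sweep draws, in order:
#' latent scores \eqn{\eta_i} from their normal full conditional (precision
#' \eqn{\Phi^{-1} + \sum_j \lambda_j^2/\psi_j}); intercepts and loadings
#' from normal–normal conjugacy against their priors; and residual
#' variances from \eqn{\mathrm{IG}(a_j + N/2,\, b_j + \mathrm{SSE}_j/2)}
#' with \eqn{\mathrm{SSE}_j = \sum_i (X_{ij} - \tau_j - \lambda_j\eta_i)^2}.
#' Burn-in draws are discarded and thinning applied per chain.
#'
#' Sign identification: the likelihood is invariant to jointly reflecting
#' all loadings and latent scores. Positive-centered priors break the tie in
#' practice; as a guard, any chain whose retained mean summed loading is
#' negative is reflected, and chains with mixed-sign summed loadings are
#' flagged with a warning.
#'
#' @param data Data frame or matrix of item responses.
#' @param prior An `lfm_prior`; default [prior_diffuse()].
#' @param chains Number of chains (>= 2 for [psrf()]). Default 3.
#' @param iterations Sweeps per chain. Default 5000.
#' @param burnin Discarded initial sweeps per chain. Default 1000.
#' @param thin Keep every `thin`-th post-burn-in sweep. Default 4.
#' @param seed Optional integer seed; chains run on spawned child seeds.
#' @param store_eta Also store latent-score draws (memory heavy)? Default
#'   `FALSE`.
#' @return An `lfm_posterior` object: `draws` is a list of per-chain
#'   matrices (rows = retained sweeps, columns `tau_1..tau_J, lambda_1..,
#'   psi_1..`), plus the schedule, the prior, and `psrf` per parameter.
#' @examples
#' X <- sim_responses(sim_params(0.6, 5, seed = 1), n = 200, seed = 2)
#' post <- gibbs_lfm(X, chains = 2, iterations = 500, burnin = 100,
#'                   thin = 2, seed = 3)
#' glance(post)
#' @export
gibbs_lfm <- function(data, prior = NULL, chains = 3, iterations = 5000,
                      burnin = 1000, thin = 4, seed = NULL,
                      store_eta = FALSE) {
  X <- response_matrix(data)
  N <- nrow(X)
  J <- ncol(X)
  if (is.null(prior)) prior <- prior_diffuse(J)
  stopifnot(inherits(prior, "lfm_prior"))
  if (length(prior$tau_mean) != J) abort("prior dimension does not match the number of items")
  if (iterations <= burnin) abort("`iterations` must exceed `burnin`")
  if (thin < 1) abort("`thin` must be >= 1")

  chain_seeds <- if (is.null(seed)) {
    sample.int(2147483646L, chains)
  } else {
    spawn_seeds(seed, chains)
  }

  keep_idx <- seq(burnin + thin, iterations, by = thin)
  draws <- vector("list", chains)
  eta_draws <- if (store_eta) vector("list", chains) else NULL
  for (c_ in seq_len(chains)) {
    res <- withr::with_seed(chain_seeds[c_],
                            gibbs_chain(X, prior, iterations, keep_idx, store_eta))
    draws[[c_]] <- res$params
    if (store_eta) eta_draws[[c_]] <- res$eta
  }

  # Per-chain reflection guard; flag mode-hopping chains.
  lam_cols <- J + seq_len(J)
  for (c_ in seq_len(chains)) {
    lam_sum <- rowSums(draws[[c_]][, lam_cols, drop = FALSE])
    if (any(lam_sum > 0) && any(lam_sum < 0)) {
      warn(sprintf("chain %d mixes loading signs across retained draws; interpret with care", c_))
    }
    if (mean(lam_sum) < 0) {
      draws[[c_]][, lam_cols] <- -draws[[c_]][, lam_cols]
      if (store_eta) eta_draws[[c_]] <- -eta_draws[[c_]]
    }
  }

  par_names <- c(paste0("tau_", seq_len(J)), paste0("lambda_", seq_len(J)),
                 paste0("psi_", seq_len(J)))
  for (c_ in seq_len(chains)) colnames(draws[[c_]]) <- par_names

  out <- structure(
    list(draws = draws, eta_draws = eta_draws, prior = prior,
         n_obs = N, n_items = J,
         schedule = list(chains = chains, iterations = iterations,
                         burnin = burnin, thin = thin, seed = seed)),
    class = "lfm_posterior"
  )
  out$psrf <- if (chains >= 2) psrf(out) else NULL
  out
}

# One chain; returns retained draws. RNG comes from the caller's seed scope.
gibbs_chain <- function(X, prior, iterations, keep_idx, store_eta) {
  N <- nrow(X); J <- ncol(X)
  cs_X <- colSums(X)
  tau_prec0 <- 1 / prior$tau_sd^2
  lam_prec0 <- 1 / prior$lambda_sd^2
  tau_pm <- prior$tau_mean * tau_prec0
  lam_pm <- prior$lambda_mean * lam_prec0

  # start from moment-based values: tau = item means, lambda from the
  # leading eigenpair, psi from the diagonal remainder
  tau <- cs_X / N
  S <- crossprod(sweep(X, 2, tau)) / N
  ev <- eigen(S, symmetric = TRUE)
  lambda <- ev$vectors[, 1] * sqrt(max(ev$values[1], 1e-8))
  if (sum(lambda) < 0) lambda <- -lambda
  psi <- pmax(diag(S) - lambda^2, 0.05 * diag(S))

  kept <- matrix(NA_real_, length(keep_idx), 3 * J)
  kept_eta <- if (store_eta) matrix(NA_real_, length(keep_idx), N) else NULL
  k <- 1L
  for (it in seq_len(iterations)) {
    # eta | .
    w <- lambda / psi
    prec_eta <- 1 + sum(lambda * w)
    m_eta <- (X %*% w - sum(tau * w)) / prec_eta
    eta <- rnorm(N, m_eta, 1 / sqrt(prec_eta))
    s_eta <- sum(eta)
    s_eta2 <- sum(eta^2)

    # tau | .
    t_prec <- N / psi + tau_prec0
    t_mean <- ((cs_X - lambda * s_eta) / psi + tau_pm) / t_prec
    tau <- rnorm(J, t_mean, 1 / sqrt(t_prec))

    # lambda | .
    cross <- as.numeric(crossprod(eta, X))
    l_prec <- s_eta2 / psi + lam_prec0
    l_mean <- ((cross - tau * s_eta) / psi + lam_pm) / l_prec
    lambda <- rnorm(J, l_mean, 1 / sqrt(l_prec))

    # psi | .
    resid <- X - rep(tau, each = N) - outer(eta, lambda)
    sse <- colSums(resid^2)
    psi <- 1 / rgamma(J, shape = prior$psi_shape + N / 2,
                      rate = prior$psi_scale + sse / 2)
    if (any(psi <= 0)) abort("non-positive residual-variance draw: numeric failure in the sampler")

    if (k <= length(keep_idx) && it == keep_idx[k]) {
      kept[k, ] <- c(tau, lambda, psi)
      if (store_eta) kept_eta[k, ] <- eta
      k <- k + 1L
    }
  }
  list(params = kept, eta = kept_eta)
}

#' @export
print.lfm_posterior <- function(x, ...) {
  s <- x$schedule
  cat(sprintf(
    "<lfm_posterior> %d items, N = %d; %d chains x %d iterations (burn-in %d, thin %d) -> %d retained draws; %s priors\n",
    x$n_items, x$n_obs, s$chains, s$iterations, s$burnin, s$thin,
    sum(vapply(x$draws, nrow, integer(1))), x$prior$label
  ))
  if (!is.null(x$psrf)) cat(sprintf("max PSRF: %.4f\n", max(x$psrf)))
  invisible(x)
}

#' Tidy posterior parameter summaries
#'
#' @param x An `lfm_posterior` object.
#' @param ... Unused.
#' @return One row per model parameter: posterior `median`, `mean`, `sd`,
#'   2.5%/97.5% equal-tail limits and `psrf`.
#' @export
tidy.lfm_posterior <- function(x, ...) {
  pooled <- do.call(rbind, x$draws)
  tibble(
    parameter = colnames(pooled),
    median = apply(pooled, 2, median),
    mean = colMeans(pooled),
    sd = apply(pooled, 2, sd),
    eq_lower = apply(pooled, 2, quantile, 0.025, names = FALSE),
    eq_upper = apply(pooled, 2, quantile, 0.975, names = FALSE),
    psrf = if (is.null(x$psrf)) NA_real_ else x$psrf
  )
}

#' @describeIn tidy.lfm_posterior one-row sampler summary (retained draws,
#'   max PSRF, schedule).
#' @export
glance.lfm_posterior <- function(x, ...) {
  s <- x$schedule
  tibble(
    n_obs = x$n_obs, n_items = x$n_items, chains = s$chains,
    iterations = s$iterations, burnin = s$burnin, thin = s$thin,
    retained = sum(vapply(x$draws, nrow, integer(1))),
    max_psrf = if (is.null(x$psrf)) NA_real_ else max(x$psrf),
    prior = x$prior$label
  )
}

#' Trace plot of posterior draws
#'
#' @param object An `lfm_posterior` object.
#' @param parameters Parameter names to show; default the loadings.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lfm_posterior <- function(object, parameters = NULL, ...) {
  if (is.null(parameters)) {
    parameters <- paste0("lambda_", seq_len(object$n_items))
  }
  long <- purrr::imap_dfr(object$draws, function(d, ch) {
    df <- as_tibble(d[, parameters, drop = FALSE])
    df$chain <- factor(ch)
    df$sweep <- seq_len(nrow(d))
    tidyr::pivot_longer(df, dplyr::all_of(parameters),
                        names_to = "parameter", values_to = "value")
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sweep, y = .data$value,
                                     colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained sweep", y = "draw")
}

#' Gelman–Rubin potential scale reduction factor
#'
#' The classic (non-rank-normalized) diagnostic
#' \deqn{\hat R = \sqrt{\frac{(T-1)/T \cdot W + \bar B/T}{W}},}
#' where \eqn{W} is the mean within-chain variance and \eqn{\bar B/T} the
#' variance of the chain means. Values near 1 indicate that the chains have
#' mixed; < 1.1 is the conventional criterion.
#'
#' @param x An `lfm_posterior`, or a numeric matrix with one column per
#'   chain (rows = retained draws).
#' @return For a posterior, a named vector with one \eqn{\hat R} per
#'   parameter; for a matrix, a single value.
#' @examples
#' psrf(cbind(rnorm(500), rnorm(500)))            # ~ 1
#' psrf(cbind(rnorm(500), rnorm(500, mean = 5)))  # >> 1.1
#' @export
psrf <- function(x) {
  if (inherits(x, "lfm_posterior")) {
    if (length(x$draws) < 2) abort("PSRF needs at least 2 chains")
    P <- ncol(x$draws[[1]])
    out <- vapply(seq_len(P), function(p) {
      psrf(vapply(x$draws, function(d) d[, p], numeric(nrow(x$draws[[1]]))))
    }, numeric(1))
    return(setNames(out, colnames(x$draws[[1]])))
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("PSRF needs at least 2 chains")
  T_ <- nrow(x)
  if (T_ < 10) abort("PSRF needs at least 10 retained draws per chain")
  W <- mean(apply(x, 2, var))
  if (W == 0) abort("zero within-chain variance; PSRF undefined")
  b_over_t <- var(colMeans(x))
  sqrt(((T_ - 1) / T_ * W + b_over_t) / W)
}

#' Posterior distributions of the classification indices
#'
#' Maps every retained posterior draw \eqn{(\tau, \lambda, \psi)} through
#' the implied-moments/quadrant pipeline, yielding pooled posterior draws of
#' the four indices. Standardized (`cut_sd`) cutpoints are resolved against
#' the posterior median parameters and held fixed across draws, matching the
#' fixed-decision-rule convention of the bootstrap.
#'
#' @param posterior An `lfm_posterior` object.
#' @param cut A [cutpoints] specification.
#' @return An `index_draws` tibble (`source = "posterior"`) with one row per
#'   retained draw.
#' @examples
#' X <- sim_responses(sim_params(0.6, 5, seed = 1), n = 200, seed = 2)
#' post <- gibbs_lfm(X, chains = 2, iterations = 400, burnin = 100,
#'                   thin = 2, seed = 3)
#' posterior_indices(post, cutpoints(cut_sd = 0))
#' @export
posterior_indices <- function(posterior, cut) {
  stopifnot(inherits(posterior, "lfm_posterior"),
            inherits(cut, "cutpoint_spec"))
  pooled <- do.call(rbind, posterior$draws)
  J <- posterior$n_items
  tau_star <- rowSums(pooled[, seq_len(J), drop = FALSE])
  lambda_star <- rowSums(pooled[, J + seq_len(J), drop = FALSE])
  psi_star <- rowSums(pooled[, 2 * J + seq_len(J), drop = FALSE])

  if (is.null(cut$eta_cut) || is.null(cut$sum_cut)) {
    med <- apply(pooled, 2, median)
    med_params <- lfm_params(loadings = med[J + seq_len(J)],
                             intercepts = med[seq_len(J)],
                             residual_variances = med[2 * J + seq_len(J)])
    cut <- resolve_cutpoints(cut, implied_moments(med_params))
  }

  idx <- indices_core(tau_star, lambda_star, psi_star,
                      kappa = 0, phi = 1, cut = cut)
  new_index_draws(
    dplyr::bind_cols(tibble(draw = seq_along(tau_star)), idx),
    source = "posterior", n_failed = 0L, cut = cut
  )
}
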