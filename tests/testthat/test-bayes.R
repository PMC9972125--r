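test_that("prior constructors encode the documented specifications", {
  dif <- prior_diffuse(4)
  expect_equal(dif$tau_mean, rep(3, 4))
  expect_equal(dif$tau_sd, rep(10, 4))
  expect_equal(dif$lambda_mean, rep(1, 4))
  expect_equal(dif$lambda_sd, rep(10, 4))
  expect_equal(dif$psi_shape, rep(5, 4))
  expect_equal(dif$psi_scale, rep(10, 4))

  X <- sim_responses(sim_params(0.6, 5, seed = 41), 400, seed = 42)
  fit <- fit_lfm(X)
  emp <- prior_empirical(fit, pseudo_n = 20)
  # centers equal the ML estimates exactly; spreads are the documented ones
  expect_equal(emp$lambda_mean, fit$params$loadings)
  expect_equal(emp$tau_mean, fit$params$intercepts)
  expect_equal(emp$lambda_sd, rep(1, 5))
  expect_equal(emp$psi_shape, rep(10, 5))
  expect_equal(emp$psi_scale, 10 * fit$params$residual_variances)

  # a residual variance of 0.64 with pseudo sample size 20 maps to IG(10, 6.4)
  fake <- fit
  fake$params$residual_variances <- rep(0.64, 5)
  expect_equal(prior_empirical(fake, 20)$psi_scale, rep(6.4, 5))

  fake$converged <- FALSE
  expect_error(prior_empirical(fake), "converged")
})

test_that("each Gibbs full conditional matches a grid-normalized posterior slice", {
  # two-item toy model, tiny N: freeze all blocks but one, compare the
  # implemented conditional density against brute-force normalization of
  # the joint on a 1,000-point grid
  set.seed(43)
  X <- as.matrix(sim_responses(lfm_params(c(0.8, 0.6), intercepts = c(1, 2)),
                               6, seed = 44))
  prior <- lfm_prior(tau_mean = c(1, 2), tau_sd = 2, lambda_mean = 0.5,
                     lambda_sd = 2, psi_shape = 3, psi_scale = 2)
  eta <- rnorm(6)
  tau <- c(0.8, 2.2)
  lambda <- c(0.7, 0.5)
  psi <- c(0.5, 0.8)
  N <- 6

  check_slice <- function(grid, cond_dens, slice_logp) {
    dens_grid <- grid_density(vapply(grid, slice_logp, numeric(1)), grid)
    expect_lt(max(abs(dens_grid - cond_dens(grid))), 1e-3)
  }

  # lambda_1 | . : normal-normal conjugacy
  l_prec <- sum(eta^2) / psi[1] + 1 / prior$lambda_sd[1]^2
  l_mean <- (sum(eta * (X[, 1] - tau[1])) / psi[1] +
               prior$lambda_mean[1] / prior$lambda_sd[1]^2) / l_prec
  check_slice(seq(l_mean - 4 / sqrt(l_prec), l_mean + 4 / sqrt(l_prec),
                  length.out = 1000),
              function(g) dnorm(g, l_mean, 1 / sqrt(l_prec)),
              function(v) log_post_lfm(X, eta, tau, replace(lambda, 1, v),
                                       psi, prior))

  # tau_2 | .
  t_prec <- N / psi[2] + 1 / prior$tau_sd[2]^2
  t_mean <- (sum(X[, 2] - lambda[2] * eta) / psi[2] +
               prior$tau_mean[2] / prior$tau_sd[2]^2) / t_prec
  check_slice(seq(t_mean - 4 / sqrt(t_prec), t_mean + 4 / sqrt(t_prec),
                  length.out = 1000),
              function(g) dnorm(g, t_mean, 1 / sqrt(t_prec)),
              function(v) log_post_lfm(X, eta, replace(tau, 2, v), lambda,
                                       psi, prior))

  # eta_3 | .
  e_prec <- 1 + sum(lambda^2 / psi)
  e_mean <- sum(lambda * (X[3, ] - tau) / psi) / e_prec
  check_slice(seq(e_mean - 4 / sqrt(e_prec), e_mean + 4 / sqrt(e_prec),
                  length.out = 1000),
              function(g) dnorm(g, e_mean, 1 / sqrt(e_prec)),
              function(v) log_post_lfm(X, replace(eta, 3, v), tau, lambda,
                                       psi, prior))

  # psi_1 | . : inverse gamma with shape a + N/2, scale b + SSE/2
  sse <- sum((X[, 1] - tau[1] - lambda[1] * eta)^2)
  a_post <- prior$psi_shape[1] + N / 2
  b_post <- prior$psi_scale[1] + sse / 2
  dinvgamma <- function(g) exp(a_post * log(b_post) - lgamma(a_post) -
                                 (a_post + 1) * log(g) - b_post / g)
  ig_range <- b_post / qgamma(c(0.99999, 0.00001), shape = a_post)
  check_slice(seq(ig_range[1], ig_range[2], length.out = 1000), dinvgamma,
              function(v) log_post_lfm(X, eta, tau, lambda,
                                       replace(psi, 1, v), prior))
})

test_that("the sampler is reproducible and honours its schedule", {
  X <- sim_responses(sim_params(0.6, 5, seed = 45), 150, seed = 46)
  p1 <- gibbs_lfm(X, chains = 2, iterations = 300, burnin = 100, thin = 2,
                  seed = 47)
  p2 <- gibbs_lfm(X, chains = 2, iterations = 300, burnin = 100, thin = 2,
                  seed = 47)
  expect_identical(p1$draws, p2$draws)
  expect_identical(nrow(p1$draws[[1]]), 100L)   # (300 - 100) / 2

  # the illustration-style schedule yields 1,000 retained draws per chain
  sched <- gibbs_lfm(X, chains = 2, iterations = 5000, burnin = 1000,
                     thin = 4, seed = 48)
  expect_identical(nrow(sched$draws[[1]]), 1000L)
  expect_true(all(do.call(rbind, sched$draws)[, 11:15] > 0))  # psi draws
})

test_that("diffuse-prior posteriors wash out to the ML solution at N = 2,000", {
  p <- sim_params(0.6, 5, seed = 49)
  X <- sim_responses(p, 2000, seed = 50)
  ml <- fit_lfm(X)
  post <- gibbs_lfm(X, prior_diffuse(5), chains = 2, iterations = 1500,
                    burnin = 500, thin = 2, seed = 51)
  med <- apply(do.call(rbind, post$draws), 2, median)
  expect_lt(max(abs(med[1:5] - ml$params$intercepts)), 0.05)
  expect_lt(max(abs(med[6:10] - ml$params$loadings)), 0.05)
  expect_lt(max(abs(med[11:15] - ml$params$residual_variances)), 0.05)
  expect_true(all(post$psrf < 1.1))
})

test_that("PSRF separates mixed chains from divergent ones", {
  T_ <- 500
  set.seed(52)
  same <- cbind(rnorm(T_), rnorm(T_), rnorm(T_))
  expect_lt(psrf(same), 1.05)

  dup <- matrix(rnorm(T_), T_, 3)
  expect_equal(psrf(dup), sqrt((T_ - 1) / T_), tolerance = 1e-12)

  apart <- cbind(rnorm(T_), rnorm(T_, mean = 5))
  expect_gt(psrf(apart), 1.1)

  expect_error(psrf(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(psrf(matrix(1, 100, 2)), "within-chain variance")
})

test_that("PSRF agrees with the established diagnostic where variants coincide", {
  # coda's estimator adds a (C+1)/C sampling-variability correction to the
  # classic between/within ratio, so exact agreement is only expected when
  # chains are well mixed (both ~ 1) — and both must flag divergent chains
  skip_if_not_installed("coda")
  set.seed(53)
  mixed <- cbind(rnorm(2000), rnorm(2000))
  ref <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(mixed[, 1]),
                                           coda::mcmc(mixed[, 2])),
                           autoburnin = FALSE)$psrf[1]
  expect_equal(psrf(mixed), ref, tolerance = 0.02)

  apart <- cbind(rnorm(400), rnorm(400, mean = 3))
  ref2 <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(apart[, 1]),
                                            coda::mcmc(apart[, 2])),
                            autoburnin = FALSE)$psrf[1]
  expect_gt(psrf(apart), 1.1)
  expect_gt(ref2, 1.1)
})

test_that("posterior index draws pool chains and stay in bounds", {
  X <- sim_responses(sim_params(0.6, 5, seed = 54), 200, seed = 55)
  post <- gibbs_lfm(X, chains = 3, iterations = 600, burnin = 200, thin = 4,
                    seed = 56)
  d <- posterior_indices(post, cutpoints(cut_sd = 0))
  expect_identical(nrow(d), 300L)   # 3 chains x 100 retained
  vals <- as.matrix(d[, c("rate", "sensitivity", "specificity", "consistency")])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_identical(attr(d, "source"), "posterior")

  # near-symmetric posteriors: index of the medians ~ median of the indices
  med <- apply(do.call(rbind, post$draws), 2, median)
  med_idx <- classification_indices(
    lfm_params(loadings = med[6:10], intercepts = med[1:5],
               residual_variances = med[11:15]),
    cutpoints(cut_sd = 0))
  expect_lt(abs(median(d$rate) - med_idx$rate), 0.01)
  expect_lt(abs(median(d$consistency) - med_idx$consistency), 0.01)
})

test_that("a chance-level instrument yields chance-level posterior indices", {
  X <- sim_responses(lfm_params(rep(0, 5), residual_variances = 1), 500,
                     seed = 57)
  # with no signal the loading sign is unidentified: the mode-hop monitor
  # must flag it
  w <- capture_warnings(
    post <- gibbs_lfm(X, chains = 2, iterations = 600, burnin = 200,
                      thin = 2, seed = 58)
  )
  expect_true(all(grepl("mixes loading signs", w)))
  expect_gt(length(w), 0)
  d <- posterior_indices(post, cutpoints(cut_sd = 0))
  expect_lt(abs(median(d$rate) - 0.5), 0.1)
  expect_lt(abs(median(d$consistency) - 0.5), 0.1)
})
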