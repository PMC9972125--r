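# moments object with a chosen correlation and standard-normal margins on
# both axes, for direct quadrant checks
moments_with_rho <- function(rho) {
  tibble::tibble(
    tau_star = 0, lambda_star = NA_real_, psi_star = NA_real_,
    mu_sum = 0, var_sum = 1, rho = rho, omega = rho^2,
    latent_mean = 0, latent_variance = 1
  )
}

test_that("mean-cut quadrants match the arcsine closed form across the correlation grid", {
  cut <- cutpoints(cut_sd = 0)
  for (rho in seq(-0.9, 0.9, by = 0.1)) {
    q <- accuracy_quadrants(moments_with_rho(rho), cut)
    expect_equal(q$both_positive, orthant_mean_cut(rho), tolerance = 1e-8)
    expect_equal(q$both_negative, orthant_mean_cut(rho), tolerance = 1e-8)
    expect_equal(q$both_negative + q$neg_pos + q$pos_neg + q$both_positive, 1,
                 tolerance = 1e-8)
  }
})

test_that("independence with mean cuts puts a quarter in each quadrant", {
  q <- accuracy_quadrants(moments_with_rho(0), cutpoints(cut_sd = 0))
  expect_equal(as.numeric(q), rep(0.25, 4), tolerance = 1e-12)
  idx <- ca_indices(q)
  expect_equal(as.numeric(idx), rep(0.5, 3))
  expect_equal(cc_index(q), 0.5)
})

test_that("quadrant probabilities agree with the quadrature oracle on random triples", {
  set.seed(402)
  worst <- 0
  for (i in 1:200) {
    rho <- runif(1, -0.98, 0.98)
    zx <- runif(1, -2.5, 2.5)
    ze <- runif(1, -2.5, 2.5)
    m <- moments_with_rho(rho)
    q <- accuracy_quadrants(m, cutpoints(eta_cut = ze, sum_cut = zx))
    a_oracle <- pbvn_quadrature(zx, ze, rho)
    worst <- max(worst,
                 abs(q$both_negative - a_oracle),
                 abs(q$neg_pos - (pnorm(zx) - a_oracle)),
                 abs(q$pos_neg - (pnorm(ze) - a_oracle)),
                 abs(q$both_positive - (1 - pnorm(zx) - pnorm(ze) + a_oracle)))
    expect_equal(q$both_negative + q$neg_pos + q$pos_neg + q$both_positive, 1,
                 tolerance = 1e-8)
  }
  expect_lt(worst, 1e-7)
})

test_that("consistency quadrants are exchangeable and hit the closed form", {
  p <- lfm_params(rep(0.6, 5), intercepts = 3, residual_variances = 0.64)
  q <- consistency_quadrants(p, cutpoints(cut_sd = 0))
  # parallel forms: false-positive and false-negative corners are equal
  expect_equal(q$neg_pos, q$pos_neg, tolerance = 1e-12)
  expect_equal(cc_index(q), 0.5 + asin(9 / 12.2) / pi, tolerance = 1e-8)
  expect_equal(cc_index(q), 0.7640904, tolerance = 1e-6)

  off <- consistency_quadrants(p, cutpoints(cut_sd = 0.75))
  expect_equal(off$neg_pos, off$pos_neg, tolerance = 1e-12)
})

test_that("perfect reliability yields perfectly consistent decisions", {
  m <- tibble::tibble(tau_star = 0, lambda_star = 1, psi_star = 1e-12,
                      mu_sum = 0, var_sum = 1, rho = 1 - 1e-9,
                      omega = 1 - 1e-9, latent_mean = 0, latent_variance = 1)
  q <- consistency_quadrants(m, cutpoints(cut_sd = 0.75))
  expect_equal(q$both_negative + q$both_positive, 1, tolerance = 1e-4)
  expect_equal(cc_index(q), 1, tolerance = 1e-4)
})

test_that("a degenerate correlation is rejected with guidance", {
  expect_error(accuracy_quadrants(moments_with_rho(1), cutpoints(cut_sd = 0)),
               "degenerate")
})

test_that("index formulas follow from the quadrant masses", {
  q <- tibble::tibble(both_negative = 0.352416, neg_pos = 0.147584,
                      pos_neg = 0.147584, both_positive = 0.352416)
  idx <- ca_indices(q)
  expect_equal(idx$rate, 0.704832)
  expect_equal(idx$sensitivity, 0.704832, tolerance = 1e-6)
  expect_equal(idx$specificity, 0.704832, tolerance = 1e-6)

  perfect <- tibble::tibble(both_negative = 0.4, neg_pos = 0,
                            pos_neg = 0, both_positive = 0.6)
  expect_equal(as.numeric(ca_indices(perfect)), c(1, 1, 1))

  empty_margin <- tibble::tibble(both_negative = 0.5, neg_pos = 0,
                                 pos_neg = 0.5, both_positive = 0)
  expect_error(ca_indices(empty_margin), "B \\+ D")
})

test_that("the composed pipeline reproduces the closed-form index values", {
  p <- lfm_params(rep(0.6, 5), intercepts = 3, residual_variances = 0.64)
  idx <- classification_indices(p, cutpoints(cut_sd = 0))
  rho <- 3 / sqrt(12.2)
  expect_equal(idx$rate, 0.5 + asin(rho) / pi, tolerance = 1e-8)
  expect_equal(idx$rate, 0.8288501, tolerance = 1e-6)
  expect_equal(idx$sensitivity, idx$rate, tolerance = 1e-8)
  expect_equal(idx$specificity, idx$rate, tolerance = 1e-8)
  expect_equal(idx$consistency, 0.7640904, tolerance = 1e-6)

  chance <- classification_indices(
    lfm_params(rep(0, 5), residual_variances = 1), cutpoints(cut_sd = 0))
  expect_equal(as.numeric(chance), rep(0.5, 4), tolerance = 1e-10)
})

test_that("indices are invariant to intercept shifts under standardized cuts", {
  p1 <- lfm_params(rep(0.6, 5), intercepts = 0, residual_variances = 0.64)
  p2 <- lfm_params(rep(0.6, 5), intercepts = 7, residual_variances = 0.64)
  cut <- cutpoints(cut_sd = 0.75)
  expect_equal(classification_indices(p1, cut), classification_indices(p2, cut),
               tolerance = 1e-12)
})

test_that("flipping the positive direction swaps corners but not rate or consistency", {
  p <- sim_params(0.55, 7, seed = 9)
  up <- cutpoints(cut_sd = 0.6, direction = "above")
  dn <- cutpoints(cut_sd = 0.6, direction = "below")
  qa <- accuracy_quadrants(p, up)
  qb <- accuracy_quadrants(p, dn)
  expect_equal(qa$both_negative, qb$both_positive)
  expect_equal(qa$neg_pos, qb$pos_neg)
  ia <- classification_indices(p, up)
  ib <- classification_indices(p, dn)
  expect_equal(ia$rate, ib$rate)
  expect_equal(ia$consistency, ib$consistency)
  expect_false(isTRUE(all.equal(ia$sensitivity, ib$sensitivity)))
})

test_that("accuracy and consistency rise with their governing correlations at mean cuts", {
  cut <- cutpoints(cut_sd = 0)
  rates <- sapply(c(0.2, 0.4, 0.6, 0.8),
                  function(r) ca_indices(accuracy_quadrants(moments_with_rho(r), cut))$sensitivity)
  expect_true(all(diff(rates) > 0))
  cons <- sapply(c(0.2, 0.4, 0.6, 0.8), function(om) {
    m <- moments_with_rho(sqrt(om))
    cc_index(consistency_quadrants(m, cut))
  })
  expect_true(all(diff(cons) > 0))
})
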