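test_that("prior specs validate and sample within their supports", {
  expect_error(prior("unif", 2, 1), "min > max")
  expect_error(prior("norm", 0), "2 numeric")
  expect_error(prior("gamma", 1, 1))
  expect_error(default_priors(foo = prior("fixed", 1)), "unknown prior")

  pr <- default_priors()
  set.seed(20)
  d <- sample_priors(pr, 5000)
  expect_true(all(d$r_max >= 0 & d$r_max <= 0.11))
  expect_true(all(d$n_recent >= 100 & d$n_recent <= 10000))
  expect_true(all(d$p_msy >= 0.5 & d$p_msy <= 0.8))
  expect_true(all(d$sigma2 >= 6.5e-5 & d$sigma2 <= 6.5e-4))
  expect_true(all(d$pi >= 0 & d$pi <= 1))
  expect_true(all(d$beta == 0))
  expect_equal(mean(d$slr1), 1.6, tolerance = 0.01)
  expect_equal(mean(d$slr2), 1.09, tolerance = 0.01)
  # truncated lognormal respects its bounds (rejection sampling)
  tl <- sample_priors(default_priors(
    r_max = prior("tlnorm", -2.67, 0.5, 0.02, 0.11)), 2000)
  expect_true(all(tl$r_max >= 0.02 & tl$r_max <= 0.11))
  # fixed seed gives a bit-identical draw sequence
  expect_identical(sample_priors(pr, 100, seed = 7),
                   sample_priors(pr, 100, seed = 7))
})

test_that("analytic catchability is the GLS profile maximum", {
  # zero residuals: q_hat recovers q exactly for any valid sigma
  set.seed(21)
  N <- stats::runif(6, 1000, 9000)
  sigma <- random_psd(6)
  q <- 0.41
  expect_equal(analytic_q(q * N, N, sigma), q, tolerance = 1e-12)
  # identity covariance, beta = 0: q_hat is the geometric mean of A/N
  expect_equal(analytic_q(c(2, 8), c(1, 1), diag(2)), 4, tolerance = 1e-12)
  # beta shifts the regression residual
  beta <- 0.1
  expect_equal(analytic_q(q * N^(1 + beta), N, sigma, beta = beta), q,
               tolerance = 1e-10)
})

test_that("index likelihood decreases away from the fitted mean", {
  set.seed(22)
  N <- stats::runif(5, 1000, 5000)
  sigma <- diag(0.05, 5)
  A <- 0.3 * N
  base <- loglik_index(A, N, sigma)
  # perfect fit equals the MVN log-density at its mean (quadratic = 0)
  expect_equal(base, -0.5 * 5 * log(2 * pi) - 0.5 * sum(log(diag(sigma))))
  worse1 <- loglik_index(A * exp(c(0.1, 0, 0, 0, 0)), N, sigma)
  worse2 <- loglik_index(A * exp(c(0.3, 0, 0, 0, 0)), N, sigma)
  expect_gt(base, worse1)
  expect_gt(worse1, worse2)
  # beta -> 0 limit is continuous with beta = 0
  expect_equal(loglik_index(A, N, sigma, beta = 1e-9),
               loglik_index(A, N, sigma, beta = 0), tolerance = 1e-5)
  # tau2 inflates the diagonal
  expect_false(isTRUE(all.equal(loglik_index(A * 1.1, N, sigma),
                                loglik_index(A * 1.1, N, sigma,
                                             tau2 = 0.02))))
  expect_error(loglik_index(A, N, sigma * 0), "singular|positive")
})

test_that("absolute-abundance likelihood is a lognormal around N", {
  # maximised at the published estimate
  centre <- loglik_absolute(4245)
  expect_gt(centre, loglik_absolute(4245 * 1.05))
  expect_gt(centre, loglik_absolute(4245 / 1.05))
  # log-scale symmetry
  expect_equal(loglik_absolute(4245 * 1.3), loglik_absolute(4245 / 1.3))
  # variance derives from the printed SE via the CV transform
  expect_equal(log(1 + (245 / 4245)^2), 3.3256e-3, tolerance = 1e-3)
  ll <- function(n) loglik_absolute(n)
  grid <- seq(3000, 6000, by = 10)
  expect_equal(grid[which.max(vapply(grid, ll, numeric(1)))], 4250,
               tolerance = 15)
})

test_that("resampling is invariant to constant weight shifts", {
  set.seed(23)
  lw <- stats::rnorm(1000)
  i1 <- sir_resample(lw, 500, seed = 1)
  i2 <- sir_resample(lw + 123.4, 500, seed = 1)
  expect_identical(as.integer(i1), as.integer(i2))
  # concentrating the likelihood reduces the unique-draw count
  flat <- sir_resample(rep(0, 1000), 500, seed = 2)
  peaked <- sir_resample(100 * lw, 500, seed = 2)
  expect_gt(attr(flat, "n_unique"), attr(peaked, "n_unique"))
  expect_error(sir_resample(rep(-Inf, 10), 5), "all importance weights")
})

test_that("run_sir produces a well-formed posterior on synthetic data", {
  fit <- small_fit()
  expect_s3_class(fit, "srw_sir")
  expect_equal(nrow(fit$posterior), 2000)
  expect_gt(fit$n_unique, 10)
  expect_true(is.finite(fit$log_marginal))
  expect_true(fit$feasible_fraction > 0 && fit$feasible_fraction <= 1)
  p <- fit$posterior
  expect_true(all(p$k > 0))
  expect_true(all(p$qhat > 0))
  expect_equal(p$p_2021, p$n_2021 / p$k)   # ratio per draw, by definition
  expect_equal(p$p_min, p$n_min / p$k)
  expect_true(all(p$n_min <= p$n_2021 + 1e-9))
  # abundance floor: medians never fall below n_c, so per-draw minima
  # stay near or above it
  expect_true(all(p$n_min > 0))
  # stored survey abundances align with the posterior rows
  expect_equal(ncol(fit$n_surv), nrow(p))
})

test_that("post-model-pre-data equals the prior when catches are zero", {
  idx <- fake_index(c(2010, 2015), c(1000, 1100), diag(0.05, 2))
  dat <- assessment_data(
    data.frame(year = 1700:1710, c_min = 0, c_max = 0), idx,
    absolute = list(year = 2010, estimate = 4245, se = 245))
  pmpd <- post_model_pre_data(dat, n_importance = 6000, n_out = 6000,
                              seed = 31)
  expect_equal(pmpd$feasible_fraction, 1)
  d <- pmpd$posterior
  # resampled marginals match the prior (flat weights)
  expect_equal(mean(d$r_max), 0.055, tolerance = 0.004)
  expect_equal(mean(d$pi), 0.5, tolerance = 0.02)
  expect_equal(stats::var(d$pi), 1 / 12, tolerance = 0.05)
  expect_equal(mean(d$n_recent), 5050, tolerance = 150)
})

test_that("heavy catches shift the feasible K distribution right", {
  synth <- small_synth()
  dat <- small_data()
  pmpd <- post_model_pre_data(dat, n_importance = 4000, n_out = 4000,
                              seed = 32)
  # with no catches, back-solved K would centre near the N_recent prior
  # mean (~5,000); heavy catches force far larger K
  expect_gt(stats::median(pmpd$posterior$k, na.rm = TRUE), 10000)
  expect_lte(pmpd$feasible_fraction, 1)
})

test_that("posterior catchability draws centre on the analytic estimate", {
  fit <- small_fit()
  q <- posterior_q_draws(fit, seed = 33)
  expect_true(all(q > 0))
  expect_equal(stats::median(q), stats::median(fit$posterior$qhat),
               tolerance = 0.05)
  # degenerate (near-zero) covariance returns q_hat almost exactly
  fit0 <- fit
  fit0$sigma <- diag(1e-18, nrow(fit$sigma))
  q0 <- posterior_q_draws(fit0, seed = 33)
  expect_equal(q0, fit$posterior$qhat, tolerance = 1e-6)
})
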