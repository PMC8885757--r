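test_that("residence discretization is a proper distribution", {
  p <- discretize_residence(60, 8.66, 320)
  expect_s3_class(p, "srw_residence")
  expect_equal(sum(p$p), 1, tolerance = 1e-12)
  expect_equal(which.max(p$p), 60)
  expect_true(all(p$p >= 0))
  # degenerate sd: point mass at round(mu)
  p0 <- discretize_residence(60.3, 0, 320)
  expect_equal(p0$p[60], 1)
  expect_equal(sum(p0$p), 1)
  expect_warning(discretize_residence(400, 5, 320), "truncates")
})

test_that("accumulation recursion collapses to its closed forms", {
  W <- c(rep(0, 99), stats::rpois(221, 40))
  # one-day residence: every whale leaves next day, A is the running sum
  p1 <- c(1, rep(0, 319))
  expect_equal(accumulate(W, p1)$A, cumsum(W))
  # no departures within the season: A equals W
  p0 <- rep(0, 320)
  expect_equal(accumulate(W, p0)$A, W)
  expect_error(accumulate(c(-1, W[-1]), p1), ">= 0")
})

test_that("accumulate is linear and bounds occupancy", {
  set.seed(3)
  p <- discretize_residence(20, 5, 320)
  W1 <- c(rep(0, 99), stats::runif(221, 0, 50))
  W2 <- c(rep(0, 99), stats::runif(221, 0, 30))
  a1 <- accumulate(W1, p)$A
  a2 <- accumulate(W2, p)$A
  a12 <- accumulate(2 * W1 + 3 * W2, p)$A
  expect_equal(a12, 2 * a1 + 3 * a2, tolerance = 1e-10)
  expect_gte(accumulate(W1, p)$A_total, max(W1))
  # on a coherent occupancy curve (exactly convolved from non-negative
  # arrivals and the same residence law) accumulated arrivals recover the
  # arrival series, hence are non-decreasing
  E <- c(rep(0, 99), stats::rpois(221, 10))
  surv <- c(1, 1 - cumsum(p$p))          # P(still present k days later)
  W <- vapply(1:320, function(t) sum(E[1:t] * surv[t - (1:t) + 1]),
              numeric(1))
  A <- accumulate(W, p)$A
  expect_equal(diff(c(0, A)), E, tolerance = 1e-8)
  expect_true(all(diff(A) >= -1e-8))
})

test_that("ledger conserves whales exactly: E - S = dW", {
  set.seed(4)
  p <- discretize_residence(60, 8.66, 320)
  W <- c(rep(0, 99), stats::rgamma(221, 5, 0.1))
  led <- arrival_departure_ledger(W, p)
  expect_equal(led$E - led$S, diff(c(0, W)), tolerance = 1e-9)
  # total arrivals from the ledger match the accumulation recursion
  expect_equal(sum(led$E), accumulate(W, p)$A_total, tolerance = 1e-9)
})

test_that("recursion inverts a simulated arrival process", {
  # brute-force oracle: whales arrive on known days, stay for residence
  # times drawn from p; the recursion applied to the occupancy curve must
  # recover total arrivals within Monte-Carlo error
  set.seed(5)
  n <- 20000
  p <- discretize_residence(60, 8.66, 320)
  arr <- sample(100:260, n, replace = TRUE,
                prob = stats::dnorm(100:260, 180, 30))
  stay <- sample.int(320, n, replace = TRUE, prob = p$p)
  W <- vapply(1:320, function(t) sum(arr <= t & arr + stay > t), numeric(1))
  est <- accumulate(W, p)$A_total
  expect_lt(abs(est - n) / n, 0.02)
})

test_that("daily-count model recovers a known seasonal curve", {
  set.seed(6)
  years <- 2001:2010
  a <- -20; c1 <- 0.25; d <- -0.0006  # peak near day 208
  gen <- function() {
    b <- stats::rnorm(length(years), 0, 0.3)
    do.call(rbind, lapply(seq_along(years), function(i) {
      t <- round(seq(120, 300, length.out = 8))
      mu <- exp(a + b[i] + c1 * t + d * t^2)
      data.frame(year = years[i], julian_day = t,
                 count = stats::rnbinom(length(t), mu = mu, size = 8))
    }))
  }
  # Wald 95% intervals cover the true day coefficients at roughly the
  # nominal rate across replicate fits
  cover <- replicate(20, {
    fit <- fit_daily_model(gen())
    se <- sqrt(diag(fit$vcov))
    c(abs(fit$coef[["t"]] - c1) / se[["t"]] < 1.96,
      abs(fit$coef[["I(t^2)"]] - d) / se[["I(t^2)"]] < 1.96)
  })
  expect_gte(mean(cover[1, ]), 0.75)
  expect_gte(mean(cover[2, ]), 0.75)
  fit <- fit_daily_model(gen())
  expect_s3_class(fit, "srw_daily_model")
  # predictions are clamped to zero before the season starts
  expect_equal(predict_daily(fit, years[1], days = 50), 0)
  expect_gt(predict_daily(fit, years[1], days = 208), 0)
  expect_error(fit_daily_model(transform(fit_df <- gen(),
                                         count = count + 0.5)),
               "integers")
})

test_that("single-year data fit a plain quadratic curve", {
  set.seed(7)
  t <- round(seq(120, 300, length.out = 10))
  df <- data.frame(year = 1999, julian_day = t,
                   count = stats::rnbinom(10, mu = exp(-15 + 0.2 * t -
                                                         5e-4 * t^2),
                                          size = 10))
  fit <- fit_daily_model(df)
  w <- predict_daily(fit, 1999, days = 150)
  eta <- fit$coef[["(Intercept)"]] + fit$coef[["t"]] * 150 +
    fit$coef[["I(t^2)"]] * 150^2
  expect_equal(w, exp(eta), ignore_attr = TRUE)
  expect_error(fit_daily_model(df[1, , drop = FALSE]), "2 distinct")
})

test_that("index covariance is a valid covariance and honours its seed", {
  synth <- small_synth()
  model <- fit_daily_model(synth$counts)
  p <- discretize_residence()
  idx <- index_covariance(model, p, n_rep = 120, seed = 9)
  expect_s3_class(idx, "srw_index")
  expect_equal(idx$sigma, t(idx$sigma))
  ev <- eigen(idx$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_true(all(diag(idx$sigma) > 0))
  expect_true(all(idx$A > 0))
  idx2 <- index_covariance(model, p, n_rep = 120, seed = 9)
  expect_identical(idx$sigma, idx2$sigma)
  # zero coefficient covariance propagates no uncertainty
  model0 <- model
  model0$vcov <- model$vcov * 0
  idx0 <- index_covariance(model0, p, n_rep = 120, seed = 9)
  expect_equal(max(abs(idx0$sigma)), 0, tolerance = 1e-20)
  expect_error({
    bad <- model; bad$vcov <- -diag(length(model$coef))
    index_covariance(bad, p, n_rep = 120)
  }, "positive semi-definite")
})

test_that("index round-trips through CSV with its sidecar", {
  idx <- fake_index(c(1999, 2000), c(10, 12), diag(0.02, 2))
  idx$seed <- 3L; idx$n_rep <- 100L
  f <- withr::local_tempfile(fileext = ".csv")
  write_index(idx, f)
  back <- read_index(f)
  expect_equal(back$A, idx$A, tolerance = 1e-12)
  expect_equal(unname(as.matrix(back$sigma)), unname(idx$sigma),
               tolerance = 1e-12)
  expect_equal(back$seed, 3L)
})
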