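test_that("all fifteen scenario configurations are expressible", {
  cfg <- scenario_config()
  expect_length(cfg, 15)
  expect_setequal(names(cfg), c("base", paste0("scen", 1:14)))
  expect_equal(scenario_config("base")$anchor_year, 2019)
  expect_equal(scenario_config("scen6")$anchor_year, 2004)
  expect_equal(scenario_config("scen8")$catch_series, "low")
  expect_equal(scenario_config("scen9")$catch_series, "high")
  expect_equal(scenario_config("scen7")$catch_series, "no_slr")
  expect_equal(scenario_config("scen10")$n_c, 0)
  expect_equal(scenario_config("scen11")$n_c, 75)
  expect_equal(scenario_config("scen12")$n_c, 111)
  expect_equal(scenario_config("scen1")$priors$r_max$pars, c(-2.67, 0.5))
  expect_equal(scenario_config("scen3")$priors$r_max$dist, "tlnorm")
  expect_equal(scenario_config("scen13")$priors$tau2$pars[1], log(0.2),
               tolerance = 1e-10)
  excluded <- names(Filter(function(x) !x$include_in_averaging, cfg))
  expect_setequal(excluded, c("scen4", "scen5", "scen7", "scen8", "scen9"))
  expect_error(scenario_config("scen99"), "unknown scenario id")
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"x": {"label": "a", "frobnicate": 1}}', f)
  expect_error(scenario_config("x", path = f), "unknown scenario key")
})

test_that("Bayes factors normalise marginal likelihoods", {
  bf <- bayes_factors(c(a = log(3), b = log(1)))
  expect_equal(bf$probability, c(0.75, 0.25))
  expect_equal(bf$bayes_factor_vs_best, c(1, 1 / 3))
  bf2 <- bayes_factors(c(m1 = -10, m2 = -10))
  expect_equal(bf2$probability, c(0.5, 0.5))
  # invariant to rescaling all marginals
  bf3 <- bayes_factors(c(a = log(3) + 50, b = log(1) + 50))
  expect_equal(bf3$probability, bf$probability)
  expect_equal(sum(bayes_factors(stats::rnorm(6))$probability), 1)
  expect_warning(bf4 <- bayes_factors(c(a = 0, b = NaN)), "non-finite")
  expect_equal(bf4$probability, 1)
})

test_that("model averaging pools posteriors by model probability", {
  fit <- small_fit()
  fit$scenario <- "base"
  # single included model: the averaged posterior is that model's
  avg1 <- model_average(list(fit), n_out = 500, seed = 40)
  expect_equal(sort(unique(avg1$posterior$k)) %in% fit$posterior$k,
               rep(TRUE, length(unique(avg1$posterior$k))))
  # probability 1 on one model among several: all draws come from it
  fit2 <- fit
  fit2$scenario <- "other"
  fit2$posterior$k <- fit2$posterior$k + 1e6
  avg <- model_average(list(fit, fit2), probabilities = c(1, 0),
                       n_out = 400, seed = 41)
  expect_true(all(avg$posterior$k < 1e6))
  expect_equal(unname(avg$allocation), c(400, 0))
  # allocations follow the probabilities on average
  alloc <- replicate(40, {
    model_average(list(fit, fit2), probabilities = c(0.7, 0.3),
                  n_out = 200)$allocation[1]
  })
  expect_equal(mean(alloc) / 200, 0.7, tolerance = 0.03)
  # exclusion flags are honoured
  fit2$include_in_averaging <- FALSE
  avg2 <- model_average(list(fit, fit2), n_out = 300, seed = 42)
  expect_equal(names(avg2$allocation), "base")
  expect_error(model_average(list(fit2)), "no models left")
})

test_that("posterior predictive bands are nested and collapse without noise", {
  fit <- small_fit()
  ppc <- posterior_predictive_check(fit, seed = 43)
  expect_equal(nrow(ppc), length(fit$survey_years))
  expect_true(all(ppc$q2.5 <= ppc$q25 & ppc$q25 <= ppc$q50 &
                    ppc$q50 <= ppc$q75 & ppc$q75 <= ppc$q97.5))
  expect_true(all(ppc$in_50 <= ppc$in_95))  # 50% band nested in 95%
  # zero observation covariance: the predictive distribution collapses
  # onto q_hat * N draw by draw (quantiles equal those of q_hat * N over
  # the posterior, with no added spread)
  fit0 <- fit
  fit0$sigma <- diag(1e-18, nrow(fit$sigma))
  ppc0 <- posterior_predictive_check(fit0, seed = 43,
                                     max_draws = nrow(fit$posterior))
  qn <- fit$n_surv[as.character(fit$survey_years), , drop = FALSE] *
    matrix(fit$posterior$qhat, nrow(fit$sigma), nrow(fit$posterior),
           byrow = TRUE)
  expect_equal(ppc0$q50, apply(qn, 1, stats::median), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(ppc0$q25, apply(qn, 1, stats::quantile, 0.25),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("posterior summaries are per-draw transforms", {
  fit <- small_fit()
  s <- summarize_posterior(fit)
  expect_setequal(s$parameter,
                  c("r_max", "k", "p_msy", "sigma", "qhat", "n_min",
                    "n_2021", "n_2030", "p_min", "p_2021", "p_2030"))
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
  # all-identical draws: mean = median = every percentile
  fit1 <- fit
  fit1$posterior <- fit$posterior[rep(1, 50), ]
  s1 <- summarize_posterior(fit1)
  expect_equal(s1$mean, s1$median)
  expect_equal(s1$q2.5, s1$q97.5)
  # depletion rows summarise the per-draw ratio, not a ratio of summaries
  expect_equal(s$median[s$parameter == "p_2021"],
               stats::median(fit$posterior$n_2021 / fit$posterior$k))
})

test_that("averaged quantiles stay inside the per-model envelope", {
  fit <- small_fit()
  fit$scenario <- "base"
  fit2 <- fit
  fit2$scenario <- "shifted"
  fit2$posterior$k <- fit2$posterior$k * 1.5
  avg <- model_average(list(fit, fit2), probabilities = c(0.5, 0.5),
                       n_out = 4000, seed = 44)
  qa <- stats::quantile(avg$posterior$k, c(0.25, 0.5, 0.75))
  q1 <- stats::quantile(fit$posterior$k, c(0.25, 0.5, 0.75))
  q2 <- stats::quantile(fit2$posterior$k, c(0.25, 0.5, 0.75))
  expect_true(all(qa >= pmin(q1, q2) - 1e-9 & qa <= pmax(q1, q2) + 1e-9))
})
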