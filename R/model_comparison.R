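#' Named sensitivity-scenario configurations
#'
#' The assessment is run under a Base Case plus fourteen sensitivity
#' scenarios varying the priors (growth rate, process variance, anchor
#' year), the catch series (no struck-and-lost correction, low only, high
#' only), the minimum-abundance floor (0 / 75 / 111 whales), and the
#' catchability assumptions (estimated extra observation error,
#' density-dependent catchability). Definitions are data, shipped as a JSON
#' config, so all fifteen runs go through one driver.
#'
#' Scenarios probing the process-variance upper bound and the alternative
#' catch series (scen4, scen5, scen7, scen8, scen9) are excluded from model
#' averaging: they exist only to probe sensitivity.
#'
#' @param id Scenario id (`"base"`, `"scen1"` .. `"scen14"`); `NULL`
#'   returns the full named list.
#' @param path Optional path to an alternative scenario JSON file.
#' @return A scenario config (list with `id`, `label`, `priors`,
#'   `anchor_year`, `catch_series`, `n_c`, `include_in_averaging`), or a
#'   named list of all of them.
#' @export
scenario_config <- function(id = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scenarios.json", package = "srwassess")
  }
  raw <- jsonlite::read_json(path)
  configs <- lapply(names(raw), function(nm) {
    x <- raw[[nm]]
    known <- c("label", "include_in_averaging", "priors", "anchor_year",
               "catch_series", "n_c")
    bad <- setdiff(names(x), known)
    if (length(bad)) stop("unknown scenario key(s) in '", nm, "': ",
                          paste(bad, collapse = ", "))
    pr <- list()
    if (!is.null(x$priors)) {
      pr <- lapply(x$priors, function(p) {
        do.call(prior, c(list(dist = p$dist), as.list(unlist(p$pars))))
      })
    }
    list(id = nm, label = x$label,
         include_in_averaging = isTRUE(x$include_in_averaging),
         priors = pr,
         anchor_year = if (is.null(x$anchor_year)) 2019 else x$anchor_year,
         catch_series = if (is.null(x$catch_series)) "both" else x$catch_series,
         n_c = if (is.null(x$n_c)) 72 else x$n_c)
  })
  names(configs) <- names(raw)
  if (is.null(id)) return(configs)
  if (!id %in% names(configs)) stop("unknown scenario id: ", id)
  configs[[id]]
}

#' Run one scenario of the assessment
#'
#' Applies a scenario's prior overrides, anchor year, catch-series switch
#' and abundance floor, then calls [run_sir()]. The catch-series switches
#' work through the priors: `"low"` fixes the catch parameter at 0,
#' `"high"` at 1, and `"no_slr"` fixes both struck-and-lost factors at 1.
#'
#' @param data An [assessment_data()] bundle (its anchor year is overridden
#'   by the scenario's).
#' @param config A [scenario_config()] entry or scenario id string.
#' @inheritParams run_sir
#' @return An `srw_sir` object with the scenario id attached.
#' @export
run_scenario <- function(data, config, n_importance = 200000L,
                         n_out = 20000L, seed = 1L, chunk_size = 10000L) {
  if (is.character(config)) config <- scenario_config(config)
  over <- config$priors
  switch(config$catch_series,
    both = NULL,
    low = { over$pi <- prior("fixed", 0) },
    high = { over$pi <- prior("fixed", 1) },
    no_slr = { over$slr1 <- prior("fixed", 1); over$slr2 <- prior("fixed", 1) },
    stop("unknown catch_series switch: ", config$catch_series))
  priors <- do.call(default_priors, over)
  data$anchor_year <- config$anchor_year
  fit <- run_sir(data, priors, n_importance, n_out, seed,
                 n_c = config$n_c, chunk_size = chunk_size)
  fit$scenario <- config$id
  fit$include_in_averaging <- config$include_in_averaging
  fit
}

#' Posterior model probabilities from marginal likelihoods
#'
#' With equal prior model probabilities, each model's posterior probability
#' is its marginal likelihood over the sum across models; Bayes factors are
#' reported pairwise against the best model. All runs must condition on the
#' same data. Runs with non-finite marginals are dropped with a warning.
#'
#' @param runs List of `srw_sir` fits (or a numeric vector of log marginal
#'   likelihoods).
#' @return Data frame with columns `model`, `log_marginal`, `probability`
#'   (summing to 1), and `bayes_factor_vs_best`.
#' @export
bayes_factors <- function(runs) {
  if (is.list(runs) && all(vapply(runs, inherits, logical(1), "srw_sir"))) {
    lm <- vapply(runs, `[[`, numeric(1), "log_marginal")
    nm <- vapply(seq_along(runs), function(i) {
      if (!is.null(runs[[i]]$scenario)) runs[[i]]$scenario else as.character(i)
    }, character(1))
  } else {
    lm <- as.numeric(runs)
    nm <- if (!is.null(names(runs))) names(runs) else as.character(seq_along(lm))
  }
  drop <- !is.finite(lm)
  if (any(drop)) {
    warning("dropping model(s) with non-finite marginal likelihood: ",
            paste(nm[drop], collapse = ", "))
    lm <- lm[!drop]; nm <- nm[!drop]
  }
  if (!length(lm)) stop("no models with finite marginal likelihood")
  p <- exp(lm - log_sum_exp(lm))
  data.frame(model = nm, log_marginal = lm, probability = p,
             bayes_factor_vs_best = exp(lm - max(lm)))
}

#' Bayesian model averaging over scenario runs
#'
#' Pools posterior draws across the included models by allocating the
#' output size multinomially according to the posterior model
#' probabilities, then resampling uniformly within each model's posterior.
#'
#' @param runs List of `srw_sir` fits.
#' @param probabilities Posterior model probabilities (same length as
#'   `runs`; normalized internally). Defaults to [bayes_factors()] applied
#'   to `runs`.
#' @param n_out Pooled posterior size (default 20,000).
#' @param seed Optional integer seed.
#' @param apply_inclusion Drop runs flagged `include_in_averaging = FALSE`
#'   (default TRUE).
#' @return Object of class `srw_averaged`: pooled `posterior` and `n_surv`,
#'   per-model `allocation` counts, and the probabilities used.
#' @export
model_average <- function(runs, probabilities = NULL, n_out = 20000L,
                          seed = NULL, apply_inclusion = TRUE) {
  stopifnot(is.list(runs), length(runs) >= 1)
  if (apply_inclusion) {
    keep <- vapply(runs, function(r) !isFALSE(r$include_in_averaging),
                   logical(1))
    runs <- runs[keep]
    if (!is.null(probabilities)) probabilities <- probabilities[keep]
  }
  if (!length(runs)) stop("no models left to average")
  if (is.null(probabilities)) {
    probabilities <- bayes_factors(runs)$probability
  }
  stopifnot(length(probabilities) == length(runs), all(probabilities >= 0),
            sum(probabilities) > 0)
  p <- probabilities / sum(probabilities)
  if (!is.null(seed)) set.seed(seed)
  alloc <- as.integer(stats::rmultinom(1, n_out, p))
  cols <- Reduce(intersect, lapply(runs, function(r) names(r$posterior)))
  pieces <- vector("list", length(runs))
  nsurv <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    if (alloc[i] == 0) next
    j <- sample.int(nrow(runs[[i]]$posterior), alloc[i], replace = TRUE)
    pieces[[i]] <- runs[[i]]$posterior[j, cols, drop = FALSE]
    nsurv[[i]] <- runs[[i]]$n_surv[, j, drop = FALSE]
  }
  post <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(post) <- NULL
  structure(list(
    posterior = post,
    n_surv = do.call(cbind, nsurv[!vapply(nsurv, is.null, logical(1))]),
    allocation = stats::setNames(alloc, vapply(runs, function(r) {
      if (!is.null(r$scenario)) r$scenario else "model"
    }, character(1))),
    probabilities = p,
    n_out = n_out,
    survey_years = runs[[1]]$survey_years,
    sigma = runs[[1]]$sigma,
    A = runs[[1]]$A,
    beta_fixed = runs[[1]]$beta_fixed
  ), class = "srw_averaged")
}

#' Posterior predictive check of the abundance index
#'
#' For each posterior draw, a replicate index vector is simulated from the
#' observation model, `log A_rep ~ MVN(log(q_hat * N^(1+beta)), Sigma)`,
#' and per-year predictive quantiles are compared with the observed index.
#' A well-calibrated model places roughly half the observations inside the
#' interquartile (25-75%) band.
#'
#' @param fit An `srw_sir` or `srw_averaged` object.
#' @param seed Optional integer seed.
#' @param max_draws Cap on the number of posterior draws simulated
#'   (default 2000, for speed; quantiles stabilise well before that).
#' @return Data frame per survey year: observed `A`, predictive quantiles
#'   (2.5/25/50/75/97.5%), and logical flags `in_50` and `in_95`.
#' @export
posterior_predictive_check <- function(fit, seed = NULL, max_draws = 2000L) {
  stopifnot(inherits(fit, "srw_sir") || inherits(fit, "srw_averaged"))
  if (!is.null(seed)) set.seed(seed)
  yrs <- as.character(fit$survey_years)
  N <- fit$n_surv[yrs, , drop = FALSE]
  qhat <- fit$posterior$qhat
  beta <- if (!is.null(fit$posterior$beta)) fit$posterior$beta
          else rep(fit$beta_fixed, length(qhat))
  m <- min(ncol(N), max_draws)
  pick <- if (ncol(N) > m) sample.int(ncol(N), m) else seq_len(ncol(N))
  sigma <- fit$sigma
  L <- t(chol(sigma + diag(1e-12, nrow(sigma))))
  d <- nrow(sigma)
  Arep <- matrix(NA_real_, d, length(pick))
  for (jj in seq_along(pick)) {
    j <- pick[jj]
    mu <- log(qhat[j]) + (1 + beta[j]) * log(N[, j])
    Arep[, jj] <- exp(mu + as.numeric(L %*% stats::rnorm(d)))
  }
  qs <- t(apply(Arep, 1, stats::quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  colnames(qs) <- c("q2.5", "q25", "q50", "q75", "q97.5")
  A <- fit$A
  data.frame(year = fit$survey_years, A = A, qs,
             in_50 = A >= qs[, "q25"] & A <= qs[, "q75"],
             in_95 = A >= qs[, "q2.5"] & A <= qs[, "q97.5"])
}

#' Posterior summary table of the key biological parameters
#'
#' Mean, median and 50%/95% credible intervals for the maximum growth rate,
#' carrying capacity, depletion at MSY, process-error SD, the per-draw
#' minimum abundance (1678-2019) and the recent/projected abundances with
#' their depletions. Depletions are summaries of per-draw ratios, never
#' ratios of summaries.
#'
#' @param fit An `srw_sir` or `srw_averaged` object.
#' @return Data frame with one row per parameter and columns `mean`, `sd`,
#'   `median`, `q2.5`, `q25`, `q75`, `q97.5`.
#' @export
summarize_posterior <- function(fit) {
  stopifnot(inherits(fit, "srw_sir") || inherits(fit, "srw_averaged"))
  p <- fit$posterior
  stopifnot(nrow(p) >= 1)
  vars <- list(
    r_max = p$r_max, k = p$k, p_msy = p$p_msy, sigma = sqrt(p$sigma2),
    qhat = p$qhat,
    n_min = p$n_min, n_2021 = p$n_2021, n_2030 = p$n_2030,
    p_min = p$p_min, p_2021 = p$p_2021, p_2030 = p$p_2030)
  out <- t(vapply(vars, function(x) {
    qs <- stats::quantile(x, c(0.5, 0.025, 0.25, 0.75, 0.975), na.rm = TRUE)
    c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x),
      median = qs[[1]], q2.5 = qs[[2]], q25 = qs[[3]], q75 = qs[[4]],
      q97.5 = qs[[5]])
  }, numeric(7)))
  data.frame(parameter = rownames(out), out, row.names = NULL)
}
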