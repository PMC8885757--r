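#' Assemble a data bundle for the assessment
#'
#' @param catch_bounds Data frame `year,c_min,c_max` (see
#'   [read_catch_series()]).
#' @param index An `srw_index` object (years, point index `A`, covariance
#'   `sigma` of `log A`).
#' @param absolute List with `year`, `estimate`, `se`: a single absolute
#'   abundance estimate (the study datum is 4,245 whales, SE 245, in 2010).
#' @param anchor_year Year carrying the recent-abundance prior (2019 base
#'   case).
#' @param start,end Modelled year range (default 1648-2030).
#' @return Object of class `srw_data`.
#' @export
assessment_data <- function(catch_bounds, index,
                            absolute = list(year = 2010, estimate = 4245,
                                            se = 245),
                            anchor_year = 2019, start = 1648, end = 2030) {
  catch_bounds <- validate_catch_bounds(catch_bounds)
  stopifnot(inherits(index, "srw_index"),
            all(c("year", "estimate", "se") %in% names(absolute)),
            absolute$estimate > 0, absolute$se > 0,
            anchor_year > start, anchor_year <= end,
            max(catch_bounds$year) <= 1973)
  structure(list(catch_bounds = catch_bounds, index = index,
                 absolute = absolute, anchor_year = anchor_year,
                 start = start, end = end),
            class = "srw_data")
}

#' Analytic (integrated-out) catchability
#'
#' With an improper uniform prior on `log q` and a multivariate lognormal
#' index likelihood, the likelihood maximised/integrated over q is obtained
#' by replacing q with its generalized-least-squares estimate,
#' `log q_hat = (1' Sigma^-1 r) / (1' Sigma^-1 1)` where
#' `r = log(A / N^(1+beta))`.
#'
#' @param A Observed index vector (> 0).
#' @param N Modelled abundance at the survey years (> 0).
#' @param sigma Covariance matrix of `log A` (invertible).
#' @param beta Density-dependence exponent of catchability (default 0).
#' @return The scalar `q_hat > 0`.
#' @export
analytic_q <- function(A, N, sigma, beta = 0) {
  stopifnot(length(A) == length(N), nrow(sigma) == length(A),
            all(A > 0), all(N > 0))
  Sinv <- tryCatch(solve(sigma), error = function(e)
    stop("sigma is singular: ", conditionMessage(e)))
  r <- log(A) - (1 + beta) * log(N)
  exp(sum(Sinv %*% r) / sum(Sinv))
}

# Multivariate normal log-density via Cholesky (no extra dependency).
mvn_logdens <- function(x, mean, sigma) {
  L <- tryCatch(chol(sigma), error = function(e)
    stop("covariance not positive definite: ", conditionMessage(e)))
  d <- length(x)
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

#' Log-likelihood of the relative-abundance index
#'
#' Multivariate lognormal observation model for the accumulated-arrivals
#' index: `log A ~ MVN(log(q_hat * N^(1+beta)), sigma + tau2 * I)`, with
#' catchability replaced by its analytic estimate ([analytic_q()]). The
#' optional `tau2` inflates the diagonal to absorb time-varying
#' catchability.
#'
#' @inheritParams analytic_q
#' @param tau2 Additional observation-error variance added to the diagonal
#'   (default 0).
#' @return Scalar log-likelihood (log density of `log A`).
#' @export
loglik_index <- function(A, N, sigma, beta = 0, tau2 = 0) {
  stopifnot(tau2 >= 0)
  S <- sigma + diag(tau2, nrow(sigma))
  qhat <- analytic_q(A, N, S, beta)
  mvn_logdens(log(A), log(qhat) + (1 + beta) * log(N), S)
}

#' Log-likelihood of the absolute abundance estimate
#'
#' Univariate lognormal observation model: the published estimate is
#' lognormal around the modelled abundance in its year, with log-scale
#' variance `tau0^2 = log(1 + (se/estimate)^2)` derived from the printed
#' standard error via the lognormal CV transform.
#'
#' @param n Modelled abundance in the estimate's year (> 0).
#' @param estimate Published absolute abundance (default 4245).
#' @param se Published standard error (default 245).
#' @return Scalar log-likelihood.
#' @export
loglik_absolute <- function(n, estimate = 4245, se = 245) {
  stopifnot(all(n > 0), estimate > 0, se > 0)
  tau0 <- sqrt(log(1 + (se / estimate)^2))
  stats::dlnorm(estimate, meanlog = log(n), sdlog = tau0, log = TRUE)
}

#' Importance resampling from log-weights
#'
#' Core of the SIR step, exposed on its own so it can be checked against
#' conjugate toy posteriors: draws indices with replacement with
#' probability proportional to `exp(log_weights)` (normalized internally,
#' so weights are invariant to a common constant).
#'
#' @param log_weights Vector of log importance weights (`-Inf` allowed).
#' @param n_out Number of resampled indices.
#' @param seed Optional integer seed.
#' @return Integer vector of resampled indices, with attribute `n_unique`.
#' @export
sir_resample <- function(log_weights, n_out = 20000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (all(!is.finite(log_weights))) {
    stop("all importance weights are zero: no feasible draws")
  }
  w <- exp(log_weights - max(log_weights[is.finite(log_weights)]))
  w[!is.finite(w)] <- 0
  idx <- sample.int(length(w), n_out, replace = TRUE, prob = w)
  attr(idx, "n_unique") <- length(unique(idx))
  idx
}

log_sum_exp <- function(x) {
  m <- max(x[is.finite(x)], -Inf)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Expand the catch bounds onto the modelled year grid and build the
# per-draw effective catch matrix (n_years x n_draws).
catch_matrix <- function(data, pi, slr1, slr2) {
  years <- data$start:data$end
  b <- data$catch_bounds
  c_min <- c_max <- numeric(length(years))
  m <- match(years, b$year)
  hit <- !is.na(m)
  c_min[hit] <- b$c_min[m[hit]]
  c_max[hit] <- b$c_max[m[hit]]
  base <- outer(c_min, rep(1, length(pi))) +
    outer(c_max - c_min, rep(1, length(pi))) *
      matrix(pi, length(years), length(pi), byrow = TRUE)
  era1 <- years >= 1771 & years <= 1850
  era2 <- years >= 1851 & years <= 1973
  base[era1, ] <- base[era1, , drop = FALSE] *
    matrix(slr1, sum(era1), length(pi), byrow = TRUE)
  base[era2, ] <- base[era2, , drop = FALSE] *
    matrix(slr2, sum(era2), length(pi), byrow = TRUE)
  base
}

# Vectorised index log-likelihood across draws sharing one covariance.
# logN: (n_surv x m) matrix of log abundance at survey years.
loglik_index_batch <- function(logA, logN, sigma, beta) {
  Sinv <- solve(sigma)
  ones <- rep(1, nrow(sigma))
  w <- as.numeric(Sinv %*% ones) / sum(Sinv)
  r <- logA - (1 + beta) * logN              # residual before q
  logq <- as.numeric(crossprod(w, r))        # GLS log q_hat per draw
  resid <- r - matrix(logq, nrow(r), ncol(r), byrow = TRUE)
  quad <- colSums(resid * (Sinv %*% resid))
  L <- chol(sigma)
  const <- -0.5 * nrow(sigma) * log(2 * pi) - sum(log(diag(L)))
  list(ll = const - 0.5 * quad, logq = logq)
}

#' Fit the assessment by sampling-importance-resampling
#'
#' Draws parameter vectors from the priors, back-solves carrying capacity
#' for each draw so the realized trajectory passes through the drawn recent
#' abundance at the anchor year (with a per-draw fixed vector of process
#' deviates), evaluates the index and absolute-abundance likelihoods with
#' catchability integrated out analytically, and resamples `n_out` draws
#' with replacement proportional to the importance weights. Infeasible
#' back-solves receive zero weight. The log marginal likelihood (mean raw
#' weight, reported on the log scale) feeds Bayes-factor model comparison;
#' the unique-draw count is the convergence diagnostic (a healthy full-size
#' run exceeds 10,000 unique draws).
#'
#' Importance draws are processed in chunks from one sequential RNG stream
#' seeded once at entry, so results are reproducible for a given
#' `(seed, n_importance, chunk_size)`.
#'
#' @param data An [assessment_data()] bundle.
#' @param priors An `srw_priors` set ([default_priors()]).
#' @param n_importance Number of importance draws (200,000 for full runs;
#'   use ~5,000-20,000 for tests).
#' @param n_out Posterior sample size (default 20,000).
#' @param seed Integer master seed.
#' @param n_c Minimum-abundance floor (default 72).
#' @param likelihood `"full"` (index + absolute), or `"none"` for the
#'   post-model-pre-data distribution (catch feasibility only).
#' @param chunk_size Importance draws per processing block.
#' @return Object of class `srw_sir`: `posterior` (data frame of resampled
#'   draws with derived K, q_hat, N_min, N_2021, N_2030 and depletions),
#'   `n_surv` (abundance at survey years per resampled draw), `n_unique`,
#'   `log_marginal`, `feasible_fraction`, plus run metadata.
#' @export
run_sir <- function(data, priors = default_priors(), n_importance = 200000L,
                    n_out = 20000L, seed = 1L, n_c = 72,
                    likelihood = c("full", "none"),
                    chunk_size = 10000L) {
  stopifnot(inherits(data, "srw_data"), inherits(priors, "srw_priors"),
            n_importance >= 1, n_out >= 1)
  likelihood <- match.arg(likelihood)
  years <- data$start:data$end
  n_years <- length(years)
  anchor_idx <- data$anchor_year - data$start + 1
  surv_idx <- match(data$index$years, years)
  abs_idx <- match(data$absolute$year, years)
  if (anyNA(surv_idx) || is.na(abs_idx)) {
    stop("survey or absolute-estimate years outside the modelled range")
  }
  logA <- log(as.numeric(data$index$A))
  sigma <- data$index$sigma
  tau2_estimated <- !is.null(priors$tau2)

  set.seed(seed)
  chunks <- split(seq_len(n_importance),
                  ceiling(seq_len(n_importance) / chunk_size))
  out_par <- vector("list", length(chunks))
  out_ll <- vector("list", length(chunks))
  out_nsurv <- vector("list", length(chunks))
  n_feasible <- 0

  for (ci in seq_along(chunks)) {
    m <- length(chunks[[ci]])
    th <- sample_priors(priors, m)
    th$slr1 <- pmax(th$slr1, 1e-6)
    th$slr2 <- pmax(th$slr2, 1e-6)
    z <- shape_from_pmsy(th$p_msy)
    eps <- matrix(stats::rnorm(n_years * m), n_years, m)
    cm <- catch_matrix(data, th$pi, th$slr1, th$slr2)
    sol <- sir_backsolve_batch(th$r_max, z, th$sigma2, th$n_recent,
                               cm, eps, n_c, anchor_idx - 1L, 30L,
                               1e7, 1e-8)
    feas <- sol$feasible & is.finite(sol$k)
    N <- sol$n
    n_feasible <- n_feasible + sum(feas)

    ll <- rep(-Inf, m)
    logq <- rep(NA_real_, m)
    Nsurv <- N[surv_idx, , drop = FALSE]
    ok <- feas & apply(Nsurv > 0, 2, all) & N[abs_idx, ] > 0
    ok[is.na(ok)] <- FALSE
    if (likelihood == "none") {
      ll[ok] <- 0
      if (any(ok)) {
        lq <- loglik_index_batch(logA, log(Nsurv[, ok, drop = FALSE]),
                                 sigma, unique(th$beta)[1])
        logq[ok] <- lq$logq
      }
    } else if (any(ok)) {
      if (!tau2_estimated) {
        beta_fixed <- priors$beta$dist == "fixed"
        if (beta_fixed) {
          lq <- loglik_index_batch(logA, log(Nsurv[, ok, drop = FALSE]),
                                   sigma, priors$beta$pars[1])
          ll_idx <- lq$ll
          logq[ok] <- lq$logq
        } else {
          ids <- which(ok)
          ll_idx <- numeric(length(ids))
          for (jj in seq_along(ids)) {
            j <- ids[jj]
            lq <- loglik_index_batch(logA, log(Nsurv[, j, drop = FALSE]),
                                     sigma, th$beta[j])
            ll_idx[jj] <- lq$ll
            logq[j] <- lq$logq
          }
        }
      } else {
        ids <- which(ok)
        ll_idx <- numeric(length(ids))
        for (jj in seq_along(ids)) {
          j <- ids[jj]
          Sj <- sigma + diag(th$tau2[j], nrow(sigma))
          lq <- loglik_index_batch(logA, log(Nsurv[, j, drop = FALSE]),
                                   Sj, th$beta[j])
          ll_idx[jj] <- lq$ll
          logq[j] <- lq$logq
        }
      }
      ll_abs <- loglik_absolute(N[abs_idx, ok], data$absolute$estimate,
                                data$absolute$se)
      ll[ok] <- ll_idx + ll_abs
    }

    th$z <- z
    th$k <- sol$k
    th$qhat <- exp(logq)
    post_range <- years >= 1678 & years <= 2019
    th$n_min <- suppressWarnings(apply(N[post_range, , drop = FALSE], 2, min))
    th$n_2021 <- N[match(2021, years), ]
    th$n_2030 <- N[match(2030, years), ]
    th$n_anchor <- N[anchor_idx, ]
    out_par[[ci]] <- th
    out_ll[[ci]] <- ll
    out_nsurv[[ci]] <- rbind(Nsurv, N[abs_idx, ])
  }

  par <- do.call(rbind, out_par)
  ll <- unlist(out_ll, use.names = FALSE)
  nsurv <- do.call(cbind, out_nsurv)
  rownames(nsurv) <- c(data$index$years, paste0("abs", data$absolute$year))

  idx <- sir_resample(ll, n_out)
  post <- par[idx, , drop = FALSE]
  post$p_min <- post$n_min / post$k
  post$p_2021 <- post$n_2021 / post$k
  post$p_2030 <- post$n_2030 / post$k
  rownames(post) <- NULL

  structure(list(
    posterior = post,
    n_surv = nsurv[, idx, drop = FALSE],
    n_unique = attr(idx, "n_unique"),
    log_marginal = log_sum_exp(ll) - log(length(ll)),
    feasible_fraction = n_feasible / n_importance,
    n_importance = n_importance,
    n_out = n_out,
    seed = seed,
    n_c = n_c,
    likelihood = likelihood,
    survey_years = data$index$years,
    sigma = sigma,
    A = as.numeric(data$index$A),
    beta_fixed = if (priors$beta$dist == "fixed") priors$beta$pars[1] else NA_real_
  ), class = "srw_sir")
}

#' Post-model-pre-data distribution
#'
#' The distribution of parameters induced by the priors and the catch
#' series alone (a draw survives iff its backwards solve is feasible),
#' before any abundance data enter. Comparing it with the posterior shows
#' how much updating the index and absolute estimate contribute. With zero
#' catches everywhere it equals the prior exactly.
#'
#' @inheritParams run_sir
#' @return An `srw_sir` object whose `feasible_fraction` reports the share
#'   of prior draws with a feasible back-solve.
#' @export
post_model_pre_data <- function(data, priors = default_priors(),
                                n_importance = 20000L, n_out = 20000L,
                                seed = 1L, n_c = 72,
                                chunk_size = 10000L) {
  run_sir(data, priors, n_importance, n_out, seed, n_c,
          likelihood = "none", chunk_size = chunk_size)
}

#' Posterior draws of catchability
#'
#' Catchability never enters the sampled parameter vector (it is integrated
#' out analytically), so its posterior is reconstructed per resampled draw:
#' given the draw's residual structure, `log q` is normal with mean
#' `log q_hat` (the draw's GLS estimate) and variance
#' `1 / (1' Sigma^-1 1)` (the GLS variance). A degenerate zero-variance
#' covariance returns `q_hat` exactly.
#'
#' @param fit An `srw_sir` object from [run_sir()].
#' @param seed Optional integer seed.
#' @return Numeric vector of q draws, one per posterior draw.
#' @export
posterior_q_draws <- function(fit, seed = NULL) {
  stopifnot(inherits(fit, "srw_sir"))
  if (!is.null(seed)) set.seed(seed)
  v <- 1 / sum(solve(fit$sigma))
  qhat <- fit$posterior$qhat
  if (v <= 0) return(qhat)
  stats::rlnorm(length(qhat), meanlog = log(qhat), sdlog = sqrt(v))
}

#' Export a posterior to CSV with a JSON metadata sidecar
#'
#' @param fit An `srw_sir` object.
#' @param path CSV output path (one row per resampled draw).
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path) {
  stopifnot(inherits(fit, "srw_sir"))
  utils::write.csv(fit$posterior, path, row.names = FALSE)
  jsonlite::write_json(
    list(seed = fit$seed, n_importance = fit$n_importance,
         n_out = fit$n_out, n_unique = fit$n_unique,
         log_marginal = fit$log_marginal,
         feasible_fraction = fit$feasible_fraction),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
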