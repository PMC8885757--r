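#' Fit the seasonal negative-binomial daily-count model
#'
#' Repeated aerial counts within a season trace a dome-shaped occupancy
#' curve: whales start arriving at the breeding ground in April (no
#' occupancy before Julian day 100) and leave before the end of the year.
#' The daily expected count is modelled on the log scale as a quadratic in
#' Julian day with a categorical year effect,
#' `E[count] = exp(a + b_y + c t + d t^2)`, with negative-binomial
#' observation error. Coefficients are stored with the signs fitted by the
#' regression (the sign placement seen in algebraic write-ups of this model
#' is purely notational).
#'
#' @param counts Data frame with columns `year`, `julian_day`, `count`
#'   (non-negative integers).
#' @return An object of class `srw_daily_model`: coefficients, their
#'   asymptotic covariance, the dispersion (theta), and the survey years.
#' @seealso [predict_daily()], [index_covariance()]
#' @export
fit_daily_model <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("year", "julian_day", "count") %in% names(counts)))
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("counts must be non-negative integers")
  }
  ok_days <- tapply(counts$julian_day, counts$year,
                    function(d) length(unique(d)))
  if (any(ok_days < 2)) stop("need at least 2 distinct flight days per year")
  df <- data.frame(year = factor(counts$year),
                   t = as.numeric(counts$julian_day),
                   count = as.integer(counts$count))
  form <- if (nlevels(df$year) > 1) count ~ year + t + I(t^2)
          else count ~ t + I(t^2)  # degenerate single-year design
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = df)),
    error = function(e) stop("daily-count model failed to converge: ",
                             conditionMessage(e))
  )
  structure(list(
    coef = stats::coef(fit),
    vcov = stats::vcov(fit),
    theta = fit$theta,
    years = sort(unique(counts$year)),
    converged = isTRUE(fit$converged)
  ), class = "srw_daily_model")
}

# Design row for (year, day) in the coefficient basis of fit_daily_model;
# `coef` may be a matrix (draws in columns) for simulation use.
daily_linpred <- function(coef_names, coef, year, years, t) {
  x <- numeric(length(coef_names))
  names(x) <- coef_names
  x["(Intercept)"] <- 1
  yl <- paste0("year", year)
  if (yl %in% coef_names) x[yl] <- 1
  else if (year != years[1]) stop("year ", year, " not in fitted model")
  x["t"] <- t
  x["I(t^2)"] <- t^2
  x
}

#' Predicted daily occupancy curve for one survey year
#'
#' Returns the model's expected number of whales present on each Julian day.
#' Predictions for days 1-99 are clamped to zero regardless of the fitted
#' coefficients: the whales only begin arriving in April.
#'
#' @param model A fitted [fit_daily_model()] object (or a list with the same
#'   fields and perturbed coefficients).
#' @param year Survey year (must be one of the fitted years).
#' @param days Integer vector of Julian days (default `1:320`).
#' @param coef Optional replacement coefficient vector (same basis as
#'   `model$coef`), used when propagating coefficient uncertainty.
#' @return Numeric vector `W[t]` of expected whales present, same length as
#'   `days`.
#' @export
predict_daily <- function(model, year, days = 1:320, coef = NULL) {
  stopifnot(inherits(model, "srw_daily_model") || is.list(model))
  if (is.null(coef)) coef <- model$coef
  nm <- names(model$coef)
  yl <- paste0("year", year)
  b_year <- if (yl %in% nm) coef[yl] else 0
  if (!yl %in% nm && year != model$years[1] && !year %in% model$years) {
    stop("year ", year, " was not in the fitted data")
  }
  eta <- coef["(Intercept)"] + b_year + coef["t"] * days +
    coef["I(t^2)"] * days^2
  w <- exp(as.numeric(eta))
  w[days <= 99] <- 0
  w
}

#' Discretized residence-time distribution
#'
#' The number of days an individual whale remains in the monitored area is
#' modelled as normal (published estimate: mean 60 d, sd 8.66 d) and
#' discretized onto integer days 1..`horizon` with continuity-corrected CDF
#' differences, `p_k = Phi((k + 1/2 - mu)/sd) - Phi((k - 1/2 - mu)/sd)`,
#' renormalized to sum to one. Residence is assumed independent of the day
#' of entry. `sd = 0` gives a point mass at `round(mu)`.
#'
#' @param mu Mean residence time in days (> 0).
#' @param sd Standard deviation in days (>= 0).
#' @param horizon Last day of the season (default 320).
#' @return An object of class `srw_residence` with fields `mu`, `sd`, `p`
#'   (probability masses for k = 1..horizon).
#' @export
discretize_residence <- function(mu = 60, sd = 8.66, horizon = 320L) {
  stopifnot(is.numeric(mu), mu > 0, is.numeric(sd), sd >= 0,
            horizon >= 1)
  k <- seq_len(horizon)
  if (sd == 0) {
    p <- numeric(horizon)
    j <- round(mu)
    if (j < 1 || j > horizon) stop("point mass at ", j, " outside horizon")
    p[j] <- 1
  } else {
    if (horizon < mu - 6 * sd) {
      warning("horizon truncates essentially all residence-time mass")
    }
    p <- stats::pnorm(k + 0.5, mu, sd) - stats::pnorm(k - 0.5, mu, sd)
    s <- sum(p)
    if (s <= 0) stop("no residence-time mass inside 1..horizon")
    p <- p / s
  }
  structure(list(mu = mu, sd = sd, p = p), class = "srw_residence")
}

#' Accumulated arrivals from a daily occupancy curve
#'
#' Occupancy counts cannot simply be summed over days: a whale present for
#' many days would be counted repeatedly. Deconvolving the occupancy curve
#' `W` with the residence distribution `p` gives the cumulative number of
#' distinct whales that have arrived by day x via the recursion
#' `A_x = W_x + sum_{k=1}^{x} p_k A_{x-k}`, `A_0 = 0`. The per-year index is
#' the season total `A` at the final day (new arrivals after mid-November
#' are assumed negligible, so `A_x = A_320` for days 320-365).
#'
#' @param W Non-negative daily occupancy, `W[t]` for t = 1..length(W).
#' @param p An [discretize_residence()] object, or a bare probability
#'   vector.
#' @return List with `A` (per-day accumulated arrivals) and `A_total`
#'   (the season total, `A[length(W)]`).
#' @export
accumulate <- function(W, p) {
  if (inherits(p, "srw_residence")) p <- p$p
  stopifnot(is.numeric(W), is.numeric(p))
  if (any(!is.finite(W)) || any(W < 0)) stop("W must be finite and >= 0")
  n <- length(W)
  filt <- p[seq_len(min(length(p), n))]
  A <- as.numeric(stats::filter(W, filt, method = "recursive"))
  list(A = A, A_total = A[n])
}

#' Arrival/departure ledger implied by an occupancy curve
#'
#' Recovers the daily number of whales entering (`E_t`) and leaving (`S_t`)
#' the area from the occupancy curve and the residence distribution, using
#' `E_t = dW_t + sum_k p_k E_{t-k}` and `S_t = sum_k p_k E_{t-k}`. The
#' bookkeeping identity `E_t - S_t = W_t - W_{t-1}` holds exactly and is
#' the conservation law behind the accumulation recursion.
#'
#' @inheritParams accumulate
#' @return Data frame with columns `t`, `E`, `S`, `W`.
#' @export
arrival_departure_ledger <- function(W, p) {
  if (inherits(p, "srw_residence")) p <- p$p
  n <- length(W)
  dW <- diff(c(0, W))
  filt <- p[seq_len(min(length(p), n))]
  E <- as.numeric(stats::filter(dW, filt, method = "recursive"))
  S <- E - dW
  data.frame(t = seq_len(n), E = E, S = S, W = W)
}

#' Per-year accumulated-arrivals index with simulated covariance
#'
#' Builds the relative-abundance index used by the assessment: for each
#' survey year, the fitted daily curve is accumulated to a season total
#' `A_y`; the joint uncertainty of the `log A_y` vector is obtained by
#' resampling the GLM coefficient vector from its asymptotic multivariate
#' normal and recomputing every season total per replicate. Dispersion
#' (theta) uncertainty is not propagated — only mean-model coefficients are
#' resampled — which slightly understates the covariance.
#'
#' @param model A fitted [fit_daily_model()] object.
#' @param p An [discretize_residence()] object.
#' @param n_rep Number of coefficient replicates (>= 100; default 2000).
#' @param seed Integer seed for the coefficient resampling.
#' @param horizon Final season day (default 320).
#' @return Object of class `srw_index`: `years`, `A` (point index from the
#'   point coefficients), `sigma` (covariance of `log A` across years),
#'   `n_rep`, `seed`.
#' @export
index_covariance <- function(model, p, n_rep = 2000L, seed = 1L,
                             horizon = 320L) {
  stopifnot(inherits(model, "srw_daily_model"), n_rep >= 100)
  V <- model$vcov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("coefficient covariance is not positive semi-definite")
  }
  days <- seq_len(horizon)
  years <- model$years
  point <- vapply(years, function(y) {
    accumulate(predict_daily(model, y, days), p)$A_total
  }, numeric(1))
  if (any(point <= 0)) stop("non-positive accumulated index")
  set.seed(seed)
  draws <- MASS::mvrnorm(n_rep, mu = model$coef, Sigma = V)
  Amat <- matrix(NA_real_, n_rep, length(years))
  for (r in seq_len(n_rep)) {
    cf <- draws[r, ]
    names(cf) <- names(model$coef)
    Amat[r, ] <- vapply(years, function(y) {
      accumulate(predict_daily(model, y, days, coef = cf), p)$A_total
    }, numeric(1))
  }
  sigma <- stats::cov(log(Amat))
  dimnames(sigma) <- list(years, years)
  structure(list(years = years, A = stats::setNames(point, years),
                 sigma = sigma, n_rep = n_rep, seed = seed),
            class = "srw_index")
}

#' Write an accumulated index (and its covariance) to CSV
#'
#' Writes `year,A` to `path`, the covariance matrix to `sigma_path`, and a
#' JSON sidecar recording the simulation seed and replicate count.
#'
#' @param index An `srw_index` object.
#' @param path CSV path for the index.
#' @param sigma_path CSV path for the covariance matrix.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path, sigma_path = sub("\\.csv$", "_sigma.csv", path)) {
  stopifnot(inherits(index, "srw_index"))
  utils::write.csv(data.frame(year = index$years, A = as.numeric(index$A)),
                   path, row.names = FALSE)
  utils::write.csv(as.data.frame(index$sigma), sigma_path, row.names = FALSE)
  jsonlite::write_json(list(seed = index$seed, n_rep = index$n_rep),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an accumulated index written by [write_index()]
#'
#' @param path CSV path of the index.
#' @param sigma_path CSV path of the covariance matrix.
#' @return An `srw_index` object (seed/n_rep restored from the sidecar if
#'   present).
#' @export
read_index <- function(path, sigma_path = sub("\\.csv$", "_sigma.csv", path)) {
  d <- utils::read.csv(path)
  sigma <- as.matrix(utils::read.csv(sigma_path))
  dimnames(sigma) <- list(d$year, d$year)
  meta <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  } else list(seed = NA_integer_, n_rep = NA_integer_)
  structure(list(years = d$year, A = stats::setNames(d$A, d$year),
                 sigma = sigma, n_rep = meta$n_rep, seed = meta$seed),
            class = "srw_index")
}
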