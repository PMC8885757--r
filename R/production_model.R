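#' Theta-logistic shape parameter from the depletion at MSY
#'
#' The generalized (theta-)logistic surplus production
#' `f(N) = Rmax * N * (1 - (N/K)^z)` attains its maximum at
#' `N/K = (1+z)^(-1/z)`. Given the depletion at maximum sustainable yield
#' `p_msy`, the shape `z` is the positive root of `(1+z)^(-1/z) = p_msy`,
#' found by bracketed bisection to `|dz| < 1e-10`. Valid targets lie in
#' `(exp(-1), 1)`; `p_msy = 0.5` gives the logistic case `z = 1`.
#'
#' @param p_msy Fraction of carrying capacity at which production peaks
#'   (vectorised).
#' @return Shape parameter(s) `z > 0`.
#' @seealso [pmsy_from_shape()]
#' @export
shape_from_pmsy <- function(p_msy) {
  stopifnot(is.numeric(p_msy), all(is.finite(p_msy)))
  if (any(p_msy <= exp(-1) + 1e-12 | p_msy >= 1)) {
    stop("p_msy must lie in (exp(-1), 1): no positive root exists outside")
  }
  lo <- rep(1e-12, length(p_msy))
  hi <- rep(1000, length(p_msy))
  # pmsy_from_shape is increasing in z, so plain bisection converges
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    up <- pmsy_from_shape(mid) < p_msy
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Depletion at MSY implied by a theta-logistic shape
#'
#' @param z Shape parameter(s) `z > 0`.
#' @return `(1+z)^(-1/z)`, the fraction of K at which production peaks.
#' @export
pmsy_from_shape <- function(z) {
  stopifnot(all(z > 0))
  (1 + z)^(-1 / z)
}

#' Theta-logistic surplus production
#'
#' Net annual population increase before removals,
#' `f(N) = r_max * N * (1 - (N/K)^z)`; zero at N = 0 and N = K.
#'
#' @param n Abundance (whales, vectorised).
#' @param r_max Maximum intrinsic growth rate (per year).
#' @param k Carrying capacity (whales).
#' @param z Shape parameter (see [shape_from_pmsy()]).
#' @return Surplus production in whales per year.
#' @export
surplus_production <- function(n, r_max, k, z) {
  stopifnot(all(n >= 0), k > 0, z > 0)
  r_max * n * (1 - (n / k)^z)
}

#' One median (pre-noise) step of the state process
#'
#' `N~_{y+1} = max(n_c, n_y + f(n_y) - c_eff_y)`: current abundance plus
#' surplus production minus effective removals, floored at the minimum
#' abundance `n_c` (the haplotype-based constraint, 72 whales in the base
#' case) to keep the log-state defined.
#'
#' @param n_y Realized abundance in year y.
#' @param c_eff_y Effective removals in year y (already SLR-corrected).
#' @inheritParams surplus_production
#' @param n_c Minimum-abundance floor (whales).
#' @return The median abundance for year y+1.
#' @export
step_median <- function(n_y, c_eff_y, r_max, k, z, n_c = 72) {
  pmax(n_c, n_y + surplus_production(n_y, r_max, k, z) - c_eff_y)
}

#' Minimum-abundance floor from mtDNA haplotype counts
#'
#' Maternally inherited haplotypes surviving to the present bound the
#' population bottleneck from below: each haplotype requires at least one
#' surviving female lineage, and the conventional 3x correction accounts
#' for males and non-contributing individuals. 24 haplotypes give the
#' base-case floor of 72 whales.
#'
#' @param haplotypes Number of distinct mtDNA haplotypes observed.
#' @param factor Correction multiplier (default 3).
#' @return Minimum abundance in whales.
#' @export
min_abundance_floor <- function(haplotypes, factor = 3) {
  stopifnot(haplotypes >= 0, factor > 0)
  haplotypes * factor
}

#' Project a population trajectory through the catch history
#'
#' Reference (single-draw) implementation of the state process. The
#' population is at carrying capacity before exploitation: median abundance
#' is fixed at K for the first `n_pre` years (1648-1677 by default), with
#' realized abundances fluctuating lognormally around it. Thereafter the
#' median steps forward through [step_median()] and realized abundance is
#' `n_{y+1} = N~_{y+1} * exp(sqrt(sigma2) * eps_{y+1})`. The floor applies
#' to the median, so realized abundance may dip slightly below it. Catches
#' must be zero after 1973; projection years use zero catch.
#'
#' @inheritParams surplus_production
#' @param sigma2 Process-error variance of log abundance.
#' @param n_c Minimum-abundance floor.
#' @param catches Numeric vector of effective removals, one per year
#'   `start..end` (recycled zeros allowed via a named series from
#'   [effective_catches()] expanded by the caller).
#' @param deviates Standard-normal process deviates, one per year
#'   `start..end`; zeros give the deterministic trajectory.
#' @param start,end First and last modelled year (default 1648, 2030).
#' @param n_pre Number of initial equilibrium years with median fixed at K
#'   (default 30: 1648-1677).
#' @return Data frame of class `srw_trajectory` with columns `year`,
#'   `n_tilde` (median), `n` (realized), `depletion` (`n/k`).
#' @export
project <- function(r_max, k, z, sigma2, catches, deviates, n_c = 72,
                    start = 1648, end = 2030, n_pre = 30) {
  n_years <- end - start + 1
  stopifnot(length(catches) == n_years, length(deviates) == n_years,
            k > 0, sigma2 >= 0, n_pre >= 1, n_pre < n_years)
  sig <- sqrt(sigma2)
  n_tilde <- n <- numeric(n_years)
  n_tilde[1:n_pre] <- k
  n[1:n_pre] <- k * exp(sig * deviates[1:n_pre])
  for (i in n_pre:(n_years - 1)) {
    n_tilde[i + 1] <- step_median(n[i], catches[i], r_max, k, z, n_c)
    n[i + 1] <- n_tilde[i + 1] * exp(sig * deviates[i + 1])
    if (!is.finite(n[i + 1])) {
      stop("non-finite abundance in year ", start + i)
    }
  }
  structure(data.frame(year = start:end, n_tilde = n_tilde, n = n,
                       depletion = n / k),
            class = c("srw_trajectory", "data.frame"))
}

#' Back-solve carrying capacity from a recent-abundance anchor
#'
#' The backwards parameterisation assigns a prior to a recent abundance
#' rather than to K itself: given growth/shape/noise parameters, the
#' effective catch series and a fixed vector of process deviates, this
#' finds the K whose realized trajectory passes through `n_recent` at the
#' anchor year (2019 in the base case, 2004 in the early-anchor scenario).
#' Terminal abundance is monotone non-decreasing in K with everything else
#' held fixed, so bracketed bisection applies; the bracket starts at
#' `[n_recent, k_max]` and the lower end is relaxed downward if needed.
#'
#' @inheritParams project
#' @param n_recent Target realized abundance at the anchor year.
#' @param anchor_year Year at which the trajectory must pass through
#'   `n_recent`.
#' @param k_max Upper bracket for K (default 1e7).
#' @param tol Relative tolerance on K (default 1e-8).
#' @return List with `k`, `trajectory` (the attached [project()] output at
#'   the solution), and `feasible`. When even `k_max` cannot reach
#'   `n_recent` the draw is infeasible: `k = NA`, `feasible = FALSE`.
#' @export
solve_k_backwards <- function(r_max, z, sigma2, n_recent, anchor_year,
                              catches, deviates, n_c = 72,
                              start = 1648, end = 2030, n_pre = 30,
                              k_max = 1e7, tol = 1e-8) {
  stopifnot(n_recent > 0, anchor_year >= start, anchor_year <= end)
  ai <- anchor_year - start + 1
  terminal <- function(k) {
    project(r_max, k, z, sigma2, catches, deviates, n_c, start, end,
            n_pre)$n[ai]
  }
  lo <- n_recent
  hi <- k_max
  if (terminal(hi) < n_recent) {
    return(list(k = NA_real_, trajectory = NULL, feasible = FALSE))
  }
  # relax the lower bracket when noise/zero catches put the root below it
  for (i in 1:60) {
    if (terminal(lo) <= n_recent) break
    lo <- lo / 2
  }
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (terminal(mid) < n_recent) lo <- mid else hi <- mid
  }
  k <- (lo + hi) / 2
  list(k = k,
       trajectory = project(r_max, k, z, sigma2, catches, deviates, n_c,
                            start, end, n_pre),
       feasible = TRUE)
}
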