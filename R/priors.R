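#' Tagged prior distribution specification
#'
#' Small constructor for the prior specs understood by [sample_priors()].
#' Supported distributions: `"unif"` (min, max), `"norm"` (mean, sd),
#' `"lnorm"` (meanlog, sdlog), `"tlnorm"` (meanlog, sdlog, lower, upper;
#' sampled by rejection), `"fixed"` (value).
#'
#' @param dist Distribution tag.
#' @param ... Numeric parameters as named above, in order.
#' @return Object of class `srw_prior`.
#' @export
prior <- function(dist = c("unif", "norm", "lnorm", "tlnorm", "fixed"), ...) {
  dist <- match.arg(dist)
  pars <- unlist(list(...))
  need <- switch(dist,
    unif = 2L, norm = 2L, lnorm = 2L, tlnorm = 4L, fixed = 1L)
  if (length(pars) != need || !is.numeric(pars) || anyNA(pars)) {
    stop("prior '", dist, "' needs ", need, " numeric parameter(s)")
  }
  if (dist == "unif" && pars[1] > pars[2]) stop("unif: min > max")
  if (dist %in% c("norm", "lnorm") && pars[2] < 0) stop("sd must be >= 0")
  if (dist == "tlnorm" && (pars[2] < 0 || pars[3] >= pars[4])) {
    stop("tlnorm: need sdlog >= 0 and lower < upper")
  }
  structure(list(dist = dist, pars = unname(pars)), class = "srw_prior")
}

draw_prior <- function(p, n) {
  stopifnot(inherits(p, "srw_prior"))
  q <- p$pars
  switch(p$dist,
    unif  = stats::runif(n, q[1], q[2]),
    norm  = stats::rnorm(n, q[1], q[2]),
    lnorm = stats::rlnorm(n, q[1], q[2]),
    fixed = rep(q[1], n),
    tlnorm = {
      out <- numeric(0)
      while (length(out) < n) {
        x <- stats::rlnorm(n, q[1], q[2])
        out <- c(out, x[x >= q[3] & x <= q[4]])
      }
      out[seq_len(n)]
    })
}

#' Base-case prior set for the assessment
#'
#' The default (vaguely informative) priors: `r_max ~ unif(0, 0.11)`
#' (upper bound at the maximum biologically plausible rate of increase);
#' `n_recent ~ unif(100, 10000)` on the anchor-year abundance;
#' `p_msy ~ unif(0.5, 0.8)`; `sigma2 ~ unif(6.5e-5, 6.5e-4)` (lower bound
#' from an age-structured process-error simulation, upper bound 10x the
#' lower); `slr1 ~ norm(1.6, 0.04)`, `slr2 ~ norm(1.09, 0.04)`;
#' `pi ~ unif(0, 1)`; `beta` fixed at 0 (no density dependence in
#' catchability); `tau2` absent (no extra observation error). Catchability
#' itself carries an improper uniform prior on log q and never enters the
#' sampled vector: it is integrated out analytically.
#'
#' @param ... Named `srw_prior` overrides for any of the entries above
#'   (use `tau2 = prior(...)` to switch on estimated extra observation
#'   error).
#' @return Named list of class `srw_priors`.
#' @export
default_priors <- function(...) {
  base <- list(
    r_max    = prior("unif", 0, 0.11),
    n_recent = prior("unif", 100, 10000),
    p_msy    = prior("unif", 0.5, 0.8),
    sigma2   = prior("unif", 6.5e-5, 6.5e-4),
    slr1     = prior("norm", 1.6, 0.04),
    slr2     = prior("norm", 1.09, 0.04),
    pi       = prior("unif", 0, 1),
    beta     = prior("fixed", 0),
    tau2     = NULL
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) stop("unknown prior name(s): ", paste(bad, collapse = ", "))
    for (nm in names(over)) base[[nm]] <- over[[nm]]
  }
  structure(base, class = "srw_priors")
}

#' Draw a joint sample from a prior set
#'
#' Independent draws respecting each marginal's support; truncated
#' lognormals are sampled by rejection. With a fixed seed the draw sequence
#' is reproducible bit for bit.
#'
#' @param priors An `srw_priors` list ([default_priors()]).
#' @param n Number of draws.
#' @param seed Optional integer seed (set before sampling when supplied).
#' @return Data frame with one column per non-NULL prior entry.
#' @export
sample_priors <- function(priors, n, seed = NULL) {
  stopifnot(inherits(priors, "srw_priors"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  keep <- !vapply(priors, is.null, logical(1))
  as.data.frame(lapply(priors[keep], draw_prior, n = n))
}
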