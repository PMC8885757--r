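# Shared fixtures for the test suite. Everything is generated in code;
# nothing is read from disk.

# Minimal catch-bounds table spanning a short era.
tiny_bounds <- function() {
  data.frame(year = 1700:1704,
             c_min = c(100, 0, 50, 10, 0),
             c_max = c(200, 0, 80, 10, 5))
}

# Bare index object without going through the survey fit.
fake_index <- function(years, A, sigma) {
  structure(list(years = years, A = stats::setNames(A, years),
                 sigma = sigma, n_rep = NA_integer_, seed = NA_integer_),
            class = "srw_index")
}

# Random positive-definite covariance of dimension d.
random_psd <- function(d, scale = 0.1) {
  M <- matrix(stats::rnorm(d * d), d)
  scale * (crossprod(M) / d + diag(0.5, d))
}

# Small synthetic assessment (cached across tests within a run).
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_assessment_dataset(default_truth(), seed = 42)
    }
    cache
  }
})

small_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synthetic_assessment_data(small_synth(), n_rep = 200,
                                          seed = 11)
    }
    cache
  }
})

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_sir(small_data(), n_importance = 4000, n_out = 2000,
                        seed = 5)
    }
    cache
  }
})
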