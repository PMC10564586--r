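# Shared fixtures and the independent least-squares oracle.

# the published worked example: boys' age-3 height, 2014 wave already moved
# to 2015 and the artificial prefix 10 prepended
worked_vector <- c(10, 99.1, 100.2, 101.3, 102.3, 101.9)

worked_series <- function() {
  grey_series(worked_vector, origin_year = 2000, step_years = 5,
              has_prefix = TRUE)
}

# independent oracle: the same grey regression solved by lm(), never by the
# package's closed-form path
oracle_gm <- function(x0) {
  x1 <- cumsum(x0)
  n <- length(x0)
  z <- (x1[-1] + x1[-n]) / 2
  co <- stats::coef(stats::lm(x0[-1] ~ z))
  list(a = -unname(co[2]), b = unname(co[1]))
}

random_positive_series <- function(n = 6) {
  # near-exponential positive series of the kind the model targets
  a <- stats::runif(1, -0.25, 0.25)
  c0 <- stats::runif(1, 5, 200)
  c0 * exp(-a * (0:(n - 1))) * exp(stats::rnorm(n, 0, 0.02))
}
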