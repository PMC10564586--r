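#' Accumulating generation operator (1-AGO)
#'
#' Replaces each value by the cumulative sum up to it.  This is the
#' smoothing step of grey modelling: a short noisy positive series becomes
#' a near-exponential monotone one.
#'
#' @param values non-empty numeric vector.
#' @return Cumulative sums, same length.
#' @export
#' @examples
#' ago(c(10, 99.1, 100.2, 101.3, 102.3, 101.9))
ago <- function(values) {
  stop_if(length(values) == 0, "empty input")
  cumsum(values)
}

#' Adjacent means of an accumulated sequence
#'
#' The background values of the grey differential equation:
#' `z(k) = (x1(k) + x1(k - 1)) / 2` for `k = 2..n`.  These are the
#' regressors of the least-squares step.
#'
#' @param ago_values 1-AGO sequence, length >= 2.
#' @return Numeric vector of length `n - 1`.
#' @export
adjacent_means <- function(ago_values) {
  n <- length(ago_values)
  stop_if(n < 2, "need at least 2 accumulated values")
  (ago_values[-1] + ago_values[-n]) / 2
}

#' Fit a GM(1,1) grey prediction model
#'
#' Estimates the development coefficient `a` and grey constant `b` of the
#' whitened equation `x0(k) + a z(k) = b` by least squares on the rows
#' `(-z(k), 1)`, solved in closed centred form:
#' slope `= cov(z, y) / var(z)`, `a = -slope`, `b = mean(y) + a mean(z)`.
#' The restored response function is
#' `x̂0(m) = (1 - e^a)(x0(1) - b/a) e^{-a(m-1)}` for `m >= 2`;
#' its leading coefficient is stored as `restored_coefficient`.  `a = 0`
#' (a perfectly flat series) is handled as the analytic limit, a constant
#' forecast equal to `b`.  Negative `a` means an increasing trend.
#'
#' Time slots are unit steps regardless of the calendar step, so `a` is
#' per step (per 5 years for the survey grid), never rescaled per year.
#'
#' @param series a [grey_series()], or a bare positive numeric vector
#'   (wrapped as a unit-step series starting at year 1).
#' @return An object of class `gm11` with fields `a`, `b`, `x1`
#'   (the first modelled value, prefix or real), `restored_coefficient`,
#'   `n_fit` (number of regression rows) and `series`.
#' @export
#' @examples
#' m <- gm11(c(10, 99.1, 100.2, 101.3, 102.3, 101.9))
#' m$a       # about -0.0076: slow increasing trend
#' m$b       # about 98.98
gm11 <- function(series) {
  if (is.numeric(series)) series <- grey_series(series, origin_year = 1L,
                                                step_years = 1L)
  stopifnot(inherits(series, "grey_series"))
  chk <- check_modelable(series)
  stop_if(!chk$ok, paste("series not modelable:",
                         paste(chk$messages, collapse = "; ")))
  x0 <- series$values
  z <- adjacent_means(ago(x0))
  y <- x0[-1]
  zc <- z - mean(z)
  szz <- sum(zc^2)
  stop_if(szz == 0, "singular normal equations: constant background values")
  slope <- sum(zc * y) / szz
  a <- -slope
  b <- mean(y) + a * mean(z)
  coefr <- if (a == 0) b else (1 - exp(a)) * (x0[1] - b / a)
  structure(list(a = a, b = b, x1 = x0[1],
                 restored_coefficient = coefr,
                 n_fit = length(y), series = series),
            class = "gm11")
}

#' @export
print.gm11 <- function(x, ...) {
  cat("GM(1,1) grey prediction model\n")
  cat(sprintf("  development coefficient a = %.6g  (10^3 a = %.1f, %s trend)\n",
              x$a, round_half_up(1000 * x$a, 1),
              if (x$a < 0) "increasing" else if (x$a > 0) "decreasing" else "flat"))
  cat(sprintf("  grey constant b = %.6g\n", x$b))
  cat(sprintf("  restored model: x0(m) = %.4f * exp(%.5f (m - 1)),  m >= 2\n",
              x$restored_coefficient, -x$a))
  cat(sprintf("  applicability: %s (a %s -0.3)\n", applicability(x),
              if (x$a >= -0.3) ">=" else "<"))
  invisible(x)
}

#' Restored response value at a time slot
#'
#' Evaluates `x̂0(m) = restored_coefficient * e^{-a(m-1)}` for integer
#' `m >= 2`.  Slot 1 is the initial (possibly artificial) value and is
#' never restored.  In the degenerate `a = 0` case the forecast is the
#' constant `b` at every slot.
#'
#' @param model a fitted [gm11()] model.
#' @param m integer slot index or vector of indices, all `>= 2`.
#' @return Restored values in the indicator's units.
#' @export
restored_value <- function(model, m) {
  stopifnot(inherits(model, "gm11"))
  stop_if(any(m < 2), "slot m must be >= 2: slot 1 is never restored")
  if (model$a == 0) return(rep(model$b, length(m)))
  model$restored_coefficient * exp(-model$a * (m - 1))
}

#' Fitted values and horizon forecasts
#'
#' Restores the model at every observed slot `m = 2..n` and extends it
#' `horizon_steps` further, attaching calendar years from the series' year
#' mapping.
#'
#' @param model a fitted [gm11()] model.
#' @param horizon_steps non-negative integer number of extra steps
#'   (default 2, i.e. two survey cycles).
#' @return A data frame with columns `m`, `year`, `value` and `type`
#'   (`"fitted"` for observed slots, `"predicted"` beyond them).
#' @export
#' @examples
#' m <- gm11(grey_series(c(10, 99.1, 100.2, 101.3, 102.3, 101.9),
#'                       origin_year = 2000, has_prefix = TRUE))
#' fit_and_forecast(m, horizon_steps = 2)
fit_and_forecast <- function(model, horizon_steps = 2L) {
  stopifnot(inherits(model, "gm11"))
  stop_if(horizon_steps < 0, "horizon_steps must be non-negative")
  n <- length(model$series$values)
  m <- seq(2L, n + horizon_steps)
  data.frame(m = m,
             year = series_years(model$series, m),
             value = restored_value(model, m),
             type = ifelse(m <= n, "fitted", "predicted"))
}

#' @rdname fit_and_forecast
#' @param object a fitted [gm11()] model.
#' @param ... unused.
#' @export
predict.gm11 <- function(object, horizon_steps = 2L, ...) {
  fit_and_forecast(object, horizon_steps)
}

#' Applicability class of a fitted model
#'
#' Grey-theory guidance: a development coefficient `a >= -0.3` supports
#' short- and medium-term prediction; steeper growth is outside the
#' model's reliable range.  The boundary is inclusive.
#'
#' @param model a fitted [gm11()] model.
#' @return `"short_medium_term_ok"` or `"out_of_range"`.
#' @export
applicability <- function(model) {
  stopifnot(inherits(model, "gm11"))
  if (model$a >= -0.3) "short_medium_term_ok" else "out_of_range"
}
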