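#' Per-year residual and precision table
#'
#' One row per observed year entering the regression (`m = 2..n`):
#' original value, fitted value, residual `original - fitted`, and fitting
#' precision `100 (1 - |residual| / original)` in percent.
#'
#' @param series the [grey_series()] that was fitted.
#' @param fitted restored values at `m = 2..n` (e.g. the `"fitted"` rows of
#'   [fit_and_forecast()]).
#' @return Data frame with columns `year`, `original`, `fitted`,
#'   `residual`, `precision_pct`.
#' @export
residual_table <- function(series, fitted) {
  stopifnot(inherits(series, "grey_series"))
  n <- length(series$values)
  original <- series$values[-1]
  stop_if(length(fitted) != length(original),
          "fitted length does not match the regression rows (n - 1)")
  residual <- original - fitted
  data.frame(year = series_years(series, 2:n),
             original = original, fitted = fitted, residual = residual,
             precision_pct = 100 * (1 - abs(residual) / original))
}

#' Mean relative fitting error (percent)
#'
#' Mean over the observed slots `m = 2..n` of
#' `100 |original - fitted| / original`.  Its complement to 100 is the
#' average relative precision.
#'
#' @inheritParams residual_table
#' @return Percentage (scalar).
#' @export
mean_relative_error <- function(series, fitted) {
  tab <- residual_table(series, fitted)
  mean(100 * abs(tab$residual) / tab$original)
}

#' Posterior-variance model accuracy test
#'
#' The classical grey-model adequacy check.  With `S1` the population
#' (divide-by-n) standard deviation of the original values entering the
#' regression and `S2` that of the residuals, the mean-square-error ratio
#' is `C = S2 / S1`, and the small-error probability `P` is the fraction
#' of residuals whose deviation from the mean residual is below
#' `0.6745 S1`.  `C` is unchanged by the sample-variance convention (the
#' factor cancels) but `P` is not; the population convention is used
#' throughout, and residuals are centred before the threshold comparison.
#'
#' @param series the fitted [grey_series()].
#' @param residuals residuals `original - fitted` at `m = 2..n`.
#' @return List with `c_ratio` and `small_error_probability`.
#' @export
posterior_variance_test <- function(series, residuals) {
  stopifnot(inherits(series, "grey_series"))
  original <- series$values[-1]
  stop_if(length(residuals) != length(original), "length mismatch")
  stop_if(length(residuals) < 2, "need at least 2 residuals")
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  s1 <- psd(original)
  stop_if(s1 == 0, "C undefined: original values are constant")
  s2 <- psd(residuals)
  list(c_ratio = s2 / s1,
       small_error_probability =
         mean(abs(residuals - mean(residuals)) < 0.6745 * s1))
}

#' Four-level accuracy grade of a grey model
#'
#' Grades each of the three criteria against the standard thresholds
#' (strict inequalities):
#' C ratio `< 0.35 / 0.50 / 0.65`, small-error probability
#' `> 0.95 / 0.80 / 0.70`, average relative precision
#' `> 99 / 95 / 90` percent, mapping to levels 1-3 and otherwise level 4.
#' The overall grade is the worst of the three, so a model may be graded
#' "Good" on C alone even when P and precision are "Excellent".
#'
#' @param c_ratio mean-square-error ratio C (>= 0).
#' @param small_error_probability fraction in [0, 1].
#' @param average_relative_precision percent.
#' @return List with integer `level` (1-4) and `label` (Excellent, Good,
#'   Qualified, Nonconforming).
#' @export
#' @examples
#' grade_model(0.37, 1, 99.63)  # Good (level 2), driven by C
grade_model <- function(c_ratio, small_error_probability,
                        average_relative_precision) {
  stop_if(c_ratio < 0, "c_ratio must be non-negative")
  stop_if(small_error_probability < 0 || small_error_probability > 1,
          "small_error_probability must lie in [0, 1]")
  first_level <- function(value, thresholds, higher_better) {
    ok <- if (higher_better) value > thresholds else value < thresholds
    if (any(ok)) which(ok)[1] else 4L
  }
  lc <- first_level(c_ratio, c(0.35, 0.50, 0.65), FALSE)
  lp <- first_level(small_error_probability, c(0.95, 0.80, 0.70), TRUE)
  lr <- first_level(average_relative_precision, c(99, 95, 90), TRUE)
  level <- max(lc, lp, lr)
  list(level = level,
       label = c("Excellent", "Good", "Qualified", "Nonconforming")[level])
}

#' Full diagnostics battery for a fitted model
#'
#' Convenience wrapper combining [residual_table()],
#' [mean_relative_error()], [posterior_variance_test()] and
#' [grade_model()].
#'
#' @param model a fitted [gm11()] model.
#' @return Object of class `gm11_diag`: list with `table`,
#'   `mean_relative_error`, `average_relative_precision`, `c_ratio`,
#'   `small_error_probability`, `level`, `label`.
#' @export
gm11_diagnostics <- function(model) {
  stopifnot(inherits(model, "gm11"))
  fc <- fit_and_forecast(model, horizon_steps = 0L)
  tab <- residual_table(model$series, fc$value)
  mre <- mean_relative_error(model$series, fc$value)
  pv <- posterior_variance_test(model$series, tab$residual)
  g <- grade_model(pv$c_ratio, pv$small_error_probability, 100 - mre)
  structure(list(table = tab, mean_relative_error = mre,
                 average_relative_precision = 100 - mre,
                 c_ratio = pv$c_ratio,
                 small_error_probability = pv$small_error_probability,
                 level = g$level, label = g$label),
            class = "gm11_diag")
}

#' @export
print.gm11_diag <- function(x, ...) {
  tab <- x$table
  tab$fitted <- round_half_up(tab$fitted, 1)
  tab$residual <- round_half_up(tab$residual, 1)
  tab$precision_pct <- round_half_up(tab$precision_pct, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("mean relative error %.5f%%, precision %.5f%%\n",
              x$mean_relative_error, x$average_relative_precision))
  cat(sprintf("C = %.4f, P = %.2f  ->  %s (level %d)\n",
              x$c_ratio, x$small_error_probability, x$label, x$level))
  invisible(x)
}
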