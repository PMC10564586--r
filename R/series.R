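#' Labelled survey-wave observation series
#'
#' Container for a raw survey series: an indicator measured at a set of
#' calendar years (e.g. mean height of 3-year-old boys at the five national
#' surveillance waves).  Years must be strictly increasing and all values
#' strictly positive; at least four points are required before a GM(1,1)
#' model can be built, but shorter series can be held.
#'
#' @param years integer calendar years, strictly increasing.
#' @param values positive numeric values (cm, kg, kg/m2 or %).
#' @param indicator optional label, one of `"height"`, `"weight"`,
#'   `"chest_circumference"`, `"bmi"`, `"overweight_rate"`, `"obesity_rate"`.
#' @param sex optional `"boys"` or `"girls"`.
#' @param age optional integer age in years (3-6); absent for rate series.
#' @return An object of class `obs_series`: a data frame with columns
#'   `year` and `value` and attributes `indicator`, `sex`, `age`.
#' @export
#' @examples
#' obs_series(c(2000, 2005, 2010, 2014, 2020),
#'            c(99.1, 100.2, 101.3, 102.1, 101.9),
#'            indicator = "height", sex = "boys", age = 3)
obs_series <- function(years, values, indicator = NULL, sex = NULL, age = NULL) {
  stop_if(length(years) != length(values), "years and values differ in length")
  stop_if(length(years) == 0, "empty series")
  years <- as.integer(years)
  stop_if(anyNA(years) || anyNA(values), "missing values in series")
  stop_if(any(diff(years) <= 0), "years must be strictly increasing")
  stop_if(any(values <= 0), "all values must be strictly positive")
  indicators <- c("height", "weight", "chest_circumference", "bmi",
                  "overweight_rate", "obesity_rate")
  if (!is.null(indicator)) indicator <- match.arg(indicator, indicators)
  out <- data.frame(year = years, value = as.numeric(values))
  structure(out, class = c("obs_series", "data.frame"),
            indicator = indicator, sex = sex,
            age = if (is.null(age)) NULL else as.integer(age))
}

#' Equidistant grey-modelling series
#'
#' The constant-step series GM(1,1) operates on.  Slot `m = 1` may be an
#' artificial prefix value (`has_prefix = TRUE`), in which case the first
#' real observation sits at `m = 2` and `origin_year` still refers to it:
#' `year(m) = origin_year + (m - 2) * step_years` with a prefix, and
#' `origin_year + (m - 1) * step_years` without.
#'
#' @param values positive numeric values indexed `m = 1..n`.
#' @param origin_year calendar year of the first real observation.
#' @param step_years positive integer grid step (default 5).
#' @param has_prefix whether slot 1 is an artificial prefix value.
#' @return An object of class `grey_series`.
#' @seealso [add_prefix()], [check_modelable()], [series_years()]
#' @export
grey_series <- function(values, origin_year, step_years = 5L, has_prefix = FALSE) {
  stop_if(length(values) == 0, "empty series")
  stop_if(any(values <= 0), "all values must be strictly positive")
  stop_if(step_years <= 0, "step_years must be positive")
  structure(list(values = as.numeric(values),
                 origin_year = as.integer(origin_year),
                 step_years = as.integer(step_years),
                 has_prefix = isTRUE(has_prefix)),
            class = "grey_series")
}

#' @export
print.grey_series <- function(x, ...) {
  cat(sprintf("<grey_series> n = %d%s, origin %d, step %d yr\n",
              length(x$values),
              if (x$has_prefix) " (slot 1 is an artificial prefix)" else "",
              x$origin_year, x$step_years))
  print(stats::setNames(x$values, series_years(x)))
  invisible(x)
}

#' Calendar years of a grey series
#'
#' @param series a [grey_series()].
#' @param m slot indices (default all slots).  With a prefix, slot 1 has no
#'   calendar year and is reported as `NA`.
#' @return integer years.
#' @export
series_years <- function(series, m = seq_along(series$values)) {
  off <- if (series$has_prefix) 2L else 1L
  y <- series$origin_year + (m - off) * series$step_years
  if (series$has_prefix) y[m == 1L] <- NA_integer_
  as.integer(y)
}

#' Move survey waves onto an equidistant year grid
#'
#' The national surveys are five-yearly except one wave (2014) taken a year
#' short of the grid.  That single off-grid observation is moved forward to
#' the next grid year by linear extrapolation along the slope of the
#' preceding inter-survey gap:
#' `value(g) = value(y) + (value(y) - value(p)) * (g - y) / (y - p)`,
#' where `p` is the previous on-grid year.  On-grid observations pass
#' through unchanged.  (Interpolating toward the following wave would not
#' reproduce the published adjusted value 102.3 cm for 2015.)
#'
#' @param series an [obs_series()].
#' @param step_years grid step in years (default 5).
#' @return A [grey_series()] without prefix.
#' @export
#' @examples
#' s <- obs_series(c(2000, 2005, 2010, 2014, 2020),
#'                 c(99.1, 100.2, 101.3, 102.1, 101.9))
#' to_equidistant(s)$values  # 102.1 in 2014 becomes 102.3 in 2015
to_equidistant <- function(series, step_years = 5L) {
  stopifnot(inherits(series, "obs_series"))
  years <- series$year
  vals <- series$value
  origin <- years[1]
  on_grid <- (years - origin) %% step_years == 0
  if (all(on_grid)) {
    gaps <- diff(years)
    stop_if(any(gaps != step_years),
            "on-grid years are not consecutive multiples of the step")
    return(grey_series(vals, origin, step_years))
  }
  stop_if(sum(!on_grid) > 1,
          "unsupported layout: more than one off-grid observation")
  i <- which(!on_grid)
  stop_if(i == 1, "unsupported layout: first observation is off-grid")
  g <- origin + step_years * ceiling((years[i] - origin) / step_years)
  p <- years[i - 1]
  stop_if((p - origin) %% step_years != 0,
          "unsupported layout: off-grid point not preceded by an on-grid point")
  v <- vals[i] + (vals[i] - vals[i - 1]) * (g - years[i]) / (years[i] - p)
  stop_if(v <= 0, "extrapolated value is non-positive; series rejected")
  years[i] <- g
  vals[i] <- v
  stop_if(any(diff(years) != step_years),
          "unsupported layout: grid not equidistant after adjustment")
  grey_series(vals, origin, step_years)
}

#' Prepend an artificial prefix value
#'
#' GM(1,1) never restores slot `m = 1`; prepending an arbitrary positive
#' value lets every real observation enter the regression.  Forecasts are
#' provably invariant to the prefix value (the adjacent-mean sequence
#' shifts by a constant, which moves only the intercept), so the default 10
#' is a convention, not a tuning knob.
#'
#' @param series a [grey_series()] without prefix.
#' @param prefix_value positive value for slot 1 (default 10).
#' @return The prefixed [grey_series()]; `origin_year` is unchanged.
#' @export
add_prefix <- function(series, prefix_value = 10) {
  stopifnot(inherits(series, "grey_series"))
  stop_if(series$has_prefix, "series already has a prefix")
  stop_if(prefix_value <= 0, "prefix value must be strictly positive")
  grey_series(c(prefix_value, series$values), series$origin_year,
              series$step_years, has_prefix = TRUE)
}

#' Check a series is modelable by GM(1,1)
#'
#' A grey model needs at least four real observations, all strictly
#' positive, on a constant step.  Returns a report rather than erroring so
#' pipelines can surface every violation at once.
#'
#' @param series a [grey_series()], or a bare numeric vector (taken as a
#'   non-prefixed unit-step series — the constructor enforces positivity,
#'   so raw candidate values can only be screened here).
#' @return A list with `ok` (logical) and `messages` (character).
#' @export
check_modelable <- function(series) {
  if (is.numeric(series))
    series <- list(values = as.numeric(series), has_prefix = FALSE,
                   step_years = 1L)
  stop_if(is.null(series$values), "not a series")
  msgs <- character()
  n_real <- length(series$values) - as.integer(series$has_prefix)
  if (n_real < 4)
    msgs <- c(msgs, sprintf("fewer than 4 data: %d real observations", n_real))
  if (any(series$values <= 0))
    msgs <- c(msgs, "non-positive values present")
  if (series$step_years <= 0)
    msgs <- c(msgs, "non-positive step")
  list(ok = length(msgs) == 0, messages = msgs)
}
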