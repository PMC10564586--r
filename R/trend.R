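#' Fit one sex/age/indicator anthropometry series
#'
#' The published modelling recipe for a five-wave anthropometry series:
#' move the short 2014 wave onto the five-year grid ([to_equidistant()]),
#' prepend the artificial prefix ([add_prefix()]), fit [gm11()] and
#' forecast two cycles ahead (2025, 2030).
#'
#' @param means data frame as returned by [cnpfs_means()].
#' @param indicator,sex,age series key.
#' @param horizon_steps forecast steps beyond the observed waves (default 2).
#' @param prefix_value artificial first value (default 10; forecasts are
#'   invariant to it).
#' @param step_years grid step (default 5).
#' @return Object of class `gm11_forecast`: list with `key`, `model`,
#'   `fitted` and `predicted` data frames (`year`, `value`),
#'   `fitting_error` (mean relative error, percent) and `diagnostics`.
#'   A development coefficient below -0.3 attaches a warning.
#' @export
#' @examples
#' rec <- fit_indicator_series(cnpfs_means(), "height", "boys", 3)
#' round_half_up(rec$fitted$value, 1)
fit_indicator_series <- function(means, indicator, sex, age,
                                 horizon_steps = 2L, prefix_value = 10,
                                 step_years = 5L) {
  rows <- means[means$indicator == indicator & means$sex == sex &
                  means$age == age, ]
  stop_if(nrow(rows) == 0,
          sprintf("no fixture series for (%s, %s, %s)", indicator, sex, age))
  rows <- rows[order(rows$year), ]
  obs <- obs_series(rows$year, rows$mean, indicator = indicator,
                    sex = sex, age = age)
  gs <- add_prefix(to_equidistant(obs, step_years), prefix_value)
  model <- gm11(gs)
  if (applicability(model) == "out_of_range")
    warning(sprintf("development coefficient a = %.4f below -0.3: %s",
                    model$a, "outside the short/medium-term range"))
  fc <- fit_and_forecast(model, horizon_steps)
  diag <- gm11_diagnostics(model)
  structure(list(key = list(indicator = indicator, sex = sex, age = age),
                 model = model,
                 observed = data.frame(year = obs$year, value = obs$value),
                 fitted = fc[fc$type == "fitted", c("year", "value")],
                 predicted = fc[fc$type == "predicted", c("year", "value")],
                 fitting_error = diag$mean_relative_error,
                 diagnostics = diag),
            class = "gm11_forecast")
}

#' Model value of a forecast record at a calendar year
#'
#' Looks the year up among the record's fitted and predicted values,
#' falling back to the observed value for years the model does not restore
#' (the first wave of a non-prefixed fit).
#'
#' @param record a `gm11_forecast` record.
#' @param year calendar year(s).
#' @return numeric value(s) in the indicator's units.
#' @export
forecast_value <- function(record, year) {
  all <- rbind(record$fitted, record$predicted)
  i <- match(year, all$year)
  if (anyNA(i)) {
    j <- match(year[is.na(i)], record$observed$year)
    stop_if(anyNA(j), sprintf("year %s not in record",
                              paste(year[is.na(i)][is.na(j)], collapse = ", ")))
    all <- rbind(all, record$observed[j, , drop = FALSE])
    i <- match(year, all$year)
  }
  all$value[i]
}

#' Growth deltas over the observed and forecast periods
#'
#' The published growth rows work on display-rounded values: the delta for
#' a period is the difference of the 1-d.p.-rounded endpoint values, and
#' the percent change is `100 delta / rounded start value` (also reported
#' at 1 d.p.).  Computing on unrounded values disagrees with the published
#' cells (e.g. a printed 4.1 where the unrounded difference is 4.19), so
#' the rounded-first convention is deliberate.
#'
#' @param record a [fit_indicator_series()] result with fitted 2000/2020
#'   and predicted 2030.
#' @param digits rounding digits (default 1).
#' @return Data frame with one row per period (`2020-2000`, `2030-2020`):
#'   `delta` and `percent`.
#' @export
growth_deltas <- function(record, digits = 1) {
  stopifnot(inherits(record, "gm11_forecast"))
  v <- round_half_up(forecast_value(record, c(2000, 2020, 2030)), digits)
  out <- data.frame(period = c("2020-2000", "2030-2020"),
                    delta = c(v[2] - v[1], v[3] - v[2]),
                    base = c(v[1], v[2]))
  out$percent <- round_half_up(100 * out$delta / out$base, digits)
  out$delta <- round_half_up(out$delta, digits)  # clean float dust
  out[, c("period", "delta", "percent")]
}

#' Age-averaged growth summary for one sex and indicator
#'
#' Averages the four per-age rounded deltas (ages 3-6) for a period and
#' annualizes the mean percent change by the period span in years.
#'
#' @param records list of exactly four [fit_indicator_series()] results,
#'   one per age.
#' @param period `"2020-2000"` or `"2030-2020"`.
#' @return List with `mean_delta` (1 d.p.), `annualized_pct` (percent per
#'   year, 2 d.p.) and the per-age `deltas` and `percents`.
#' @export
#' @examples
#' recs <- lapply(3:6, function(a)
#'   fit_indicator_series(cnpfs_means(), "height", "boys", a))
#' cohort_summary(recs)$mean_delta  # 3.6 cm over 2000-2020
cohort_summary <- function(records, period = "2020-2000") {
  stop_if(length(records) != 4, "need exactly four age records (ages 3-6)")
  span <- 20
  rows <- lapply(records, function(r) {
    d <- growth_deltas(r)
    d[d$period == period, ]
  })
  deltas <- vapply(rows, function(r) r$delta, numeric(1))
  pcts <- vapply(rows, function(r) r$percent, numeric(1))
  list(mean_delta = round_half_up(mean(deltas), 1),
       annualized_pct = round_half_up(mean(pcts) / span, 2),
       deltas = deltas, percents = pcts)
}

#' Body mass index
#'
#' `weight / height^2` with weight in kg and height in cm (converted to
#' metres).  Note that the BMI of mean weight and mean height is not the
#' mean of individual BMIs; published mean BMI may differ in the second
#' decimal.
#'
#' @param weight_kg weight in kilograms (> 0).
#' @param height_cm height in centimetres (> 0).
#' @return BMI in kg/m2.
#' @export
bmi <- function(weight_kg, height_cm) {
  stop_if(any(weight_kg <= 0) || any(height_cm <= 0),
          "weight and height must be strictly positive")
  weight_kg / (height_cm / 100)^2
}

#' Forecast an overweight/obesity detection-rate series
#'
#' The rate series are counted at four waves only (2000, 2005, 2010,
#' 2014).  The 2014 value is moved to the 2015 grid point by the same
#' local-slope extrapolation as the anthropometry series, and the model is
#' fitted WITHOUT prefix augmentation — the convention that reproduces the
#' published boys' obesity projections (with a prefix they do not).
#' Slots 5-7 of the 2000-origin grid give the 2020, 2025 and 2030 values.
#'
#' @param rates data frame as returned by [cnpfs_rates()].
#' @param indicator `"overweight_rate"` or `"obesity_rate"`.
#' @param sex `"boys"` or `"girls"`.
#' @param horizon_steps steps beyond the four observed waves (default 3,
#'   reaching 2030).
#' @param step_years grid step (default 5).
#' @return A `gm11_forecast` record (see [fit_indicator_series()]).
#' @export
#' @examples
#' rec <- forecast_prevalence(cnpfs_rates(), "obesity_rate", "boys")
#' round_half_up(rec$predicted$value, 1)  # 11.0 (2020), 12.5 (2025), 14.1 (2030)
forecast_prevalence <- function(rates, indicator, sex, horizon_steps = 3L,
                                step_years = 5L) {
  rows <- rates[rates$indicator == indicator & rates$sex == sex, ]
  stop_if(nrow(rows) == 0,
          sprintf("no rate series for (%s, %s)", indicator, sex))
  rows <- rows[order(rows$year), ]
  stop_if(nrow(rows) != 4, "rate series must have exactly 4 waves")
  stop_if(any(rows$rate <= 0 | rows$rate >= 100), "rates must lie in (0, 100)")
  obs <- obs_series(rows$year, rows$rate, indicator = indicator, sex = sex)
  gs <- to_equidistant(obs, step_years)
  model <- gm11(gs)
  if (applicability(model) == "out_of_range")
    warning(sprintf("development coefficient a = %.4f below -0.3", model$a))
  fc <- fit_and_forecast(model, horizon_steps)
  diag <- gm11_diagnostics(model)
  structure(list(key = list(indicator = indicator, sex = sex, age = NULL),
                 model = model,
                 observed = data.frame(year = obs$year, value = obs$value),
                 fitted = fc[fc$type == "fitted", c("year", "value")],
                 predicted = fc[fc$type == "predicted", c("year", "value")],
                 fitting_error = diag$mean_relative_error,
                 diagnostics = diag),
            class = "gm11_forecast")
}

record_cells <- function(record, digits = 1) {
  # long-format computed cells matching the printed-table field names
  m <- record$model
  all <- rbind(record$fitted, record$predicted)
  gd <- growth_deltas(record, digits)
  fields <- c("a1e3", "b", "fit_error_pct", as.character(all$year),
              "d2020_2000", "pct_d2020_2000", "d2030_2020", "pct_d2030_2020")
  values <- c(round_half_up(1000 * m$a, digits), round_half_up(m$b, digits),
              round_half_up(record$fitting_error, digits),
              round_half_up(all$value, digits),
              gd$delta[1], gd$percent[1], gd$delta[2], gd$percent[2])
  data.frame(indicator = record$key$indicator, sex = record$key$sex,
             age = record$key$age %||% NA_integer_,
             field = fields, computed = values)
}

#' Reproduce the published model tables
#'
#' Fits every sex x age series of the four anthropometry indicators and
#' the four prevalence series, assembles their parameters, fitted values,
#' forecasts and growth rows, and compares each cell against the packaged
#' transcription of the published tables.  A cell matches when the
#' 1-d.p.-rounded computed value equals the printed one (tolerance half a
#' final digit).  Published 2030 anthropometry cells are known not to
#' follow from the pure exponential extrapolation that reproduces every
#' other column; they are reported as mismatches by design.  Deterministic:
#' repeated runs give identical output.
#'
#' @param means,rates fixture data frames (defaults: the packaged data).
#' @param digits display rounding (default 1).
#' @return List with `cells` (computed vs printed, `match` flag),
#'   `records` (all `gm11_forecast` objects keyed `indicator.sex.age`),
#'   `summary` (match counts by indicator and field group) and `errata`
#'   ([printed_errata()]).
#' @export
reproduce_tables <- function(means = cnpfs_means(), rates = cnpfs_rates(),
                             digits = 1) {
  records <- list()
  cells <- NULL
  for (ind in c("height", "weight", "chest_circumference", "bmi"))
    for (sx in c("boys", "girls"))
      for (ag in 3:6) {
        rec <- fit_indicator_series(means, ind, sx, ag)
        records[[paste(ind, sx, ag, sep = ".")]] <- rec
        cells <- rbind(cells, record_cells(rec, digits))
      }
  printed <- printed_anthropometry()
  printed$printed <- suppressWarnings(as.numeric(printed$value))
  cells <- merge(cells, printed[, c("indicator", "sex", "age", "field",
                                    "printed")],
                 by = c("indicator", "sex", "age", "field"), all.x = TRUE)

  pcells <- NULL
  for (ind in c("overweight_rate", "obesity_rate"))
    for (sx in c("boys", "girls")) {
      rec <- forecast_prevalence(rates, ind, sx)
      records[[paste(ind, sx, sep = ".")]] <- rec
      cc <- record_cells(rec, digits)
      # only forecast cells and delta rows are printed for comparison;
      # 2005-2015 printed cells are the observed inputs, not fits
      keep <- c("2020", "2025", "2030", "d2020_2000", "d2030_2020")
      pcells <- rbind(pcells, cc[cc$field %in% keep, ])
    }
  pp <- printed_prevalence()
  pp$age <- NA_integer_
  pp$printed <- suppressWarnings(as.numeric(pp$value))
  pcells <- merge(pcells, pp[, c("indicator", "sex", "age", "field",
                                 "printed")],
                  by = c("indicator", "sex", "age", "field"), all.x = TRUE)
  cells <- rbind(cells, pcells)
  cells <- cells[order(cells$indicator, cells$sex, cells$age, cells$field), ]
  cells$match <- ifelse(is.na(cells$printed), NA,
                        abs(cells$computed - cells$printed) <= 0.05 + 1e-9)
  cells$grp <- ifelse(grepl("^20", cells$field), "values", "parameters")
  summary <- stats::aggregate(match ~ indicator + grp, data = cells,
                              FUN = mean, na.rm = TRUE, na.action = stats::na.omit)
  names(summary)[names(summary) == "match"] <- "match_rate"
  list(cells = cells, records = records, summary = summary,
       errata = printed_errata())
}
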