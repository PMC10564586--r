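#' Read a year,value series from CSV
#'
#' Plain UTF-8 CSV with header `year,value`, one series per file.
#' Malformed rows, duplicate years and non-positive values are rejected
#' with the offending line number (header is line 1).
#'
#' @param path file path.
#' @param ... optional labels passed to [obs_series()] (`indicator`,
#'   `sex`, `age`).
#' @return An [obs_series()].
#' @export
read_series_csv <- function(path, ...) {
  stop_if(!file.exists(path), sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", comment.char = "#")
  stop_if(!all(c("year", "value") %in% names(raw)),
          sprintf("%s: header must contain year,value", path))
  stop_if(nrow(raw) == 0, sprintf("%s: no data rows", path))
  year <- suppressWarnings(as.numeric(raw$year))
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(year) | is.na(value) | year != floor(year))
  stop_if(length(bad) > 0,
          sprintf("%s: malformed row at line %d", path, bad[1] + 1L))
  dup <- which(duplicated(year))
  stop_if(length(dup) > 0,
          sprintf("%s: duplicate year %d at line %d", path,
                  as.integer(year[dup[1]]), dup[1] + 1L))
  neg <- which(value <= 0)
  stop_if(length(neg) > 0,
          sprintf("%s: non-positive value at line %d", path, neg[1] + 1L))
  o <- order(year)
  obs_series(year[o], value[o], ...)
}

#' Write a generated series as year,value CSV
#'
#' The same format [read_series_csv()] reads, so synthetic series feed the
#' fitting pipeline directly.  Prefix slots (no calendar year) are skipped.
#'
#' @param series a [grey_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "grey_series"))
  yrs <- series_years(series)
  keep <- !is.na(yrs)
  utils::write.csv(data.frame(year = yrs[keep], value = series$values[keep]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' The defaults reproduce the published pipeline exactly: prefix value 10
#' on five-wave anthropometry series, five-year grid, two forecast cycles,
#' one display decimal, and no prefix on the four-wave prevalence series.
#' The configuration is echoed (with a fingerprint) into every artifact
#' manifest so outputs are traceable.
#'
#' @param prefix_value artificial first value for anthropometry fits.
#' @param grid_step_years survey grid step.
#' @param horizon_steps forecast cycles beyond the observed waves.
#' @param rounding_digits display rounding.
#' @param prevalence_prefix whether prevalence fits get a prefix (the
#'   published projections require `FALSE`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(prefix_value = 10, grid_step_years = 5L,
                            horizon_steps = 2L, rounding_digits = 1L,
                            prevalence_prefix = FALSE) {
  structure(list(prefix_value = prefix_value,
                 grid_step_years = as.integer(grid_step_years),
                 horizon_steps = as.integer(horizon_steps),
                 rounding_digits = as.integer(rounding_digits),
                 prevalence_prefix = isTRUE(prevalence_prefix)),
            class = "pipeline_config")
}

config_fingerprint <- function(config) {
  paste0("greygrowth-",
         as.character(utils::packageVersion("greygrowth")), ":",
         paste(names(config), unlist(config), sep = "=", collapse = ";"))
}

#' Serialize a fitted model to JSON
#'
#' Fields: `a`, `b`, `x1`, `restored_coefficient`, `origin_year`,
#' `step_years`, `has_prefix`, `n_fit`.
#'
#' @param model a fitted [gm11()] model.
#' @param path optional output file; omitted, the JSON string is returned.
#' @return The JSON string, invisibly if written to `path`.
#' @export
model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "gm11"))
  x <- list(a = model$a, b = model$b, x1 = model$x1,
            restored_coefficient = model$restored_coefficient,
            origin_year = model$series$origin_year,
            step_years = model$series$step_years,
            has_prefix = model$series$has_prefix,
            n_fit = model$n_fit)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Run the fitting pipeline on one series and write its artifacts
#'
#' The programmatic equivalent of a `fit` command: preprocess (grid
#' adjustment, optional prefix), fit, diagnose, forecast, and write three
#' artifacts under `out_dir` — `model.json`, `diagnostics.csv`
#' (the residual table) and `forecast.csv` — plus `manifest.json`
#' recording the configuration fingerprint and every preprocessing
#' decision (adjusted year, prefix used, applicability warning).
#' Deterministic: identical inputs and config give byte-identical
#' artifacts.
#'
#' @param series an [obs_series()] or a path to a `year,value` CSV.
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param prefix whether to prepend the artificial prefix (default TRUE,
#'   the anthropometry convention; use FALSE for 4-wave rate series).
#' @return Invisible list with the fitted `model`, `diagnostics`,
#'   `forecast` and artifact `paths`.
#' @export
run_fit <- function(series, out_dir, config = pipeline_config(),
                    prefix = TRUE) {
  if (is.character(series)) series <- read_series_csv(series)
  stopifnot(inherits(series, "obs_series"), inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gs <- to_equidistant(series, config$grid_step_years)
  adjusted <- series$year[!series$year %in% series_years(gs)]
  if (prefix) gs <- add_prefix(gs, config$prefix_value)
  model <- gm11(gs)
  diag <- gm11_diagnostics(model)
  fc <- fit_and_forecast(model, config$horizon_steps)
  paths <- file.path(out_dir, c(model = "model.json",
                                diagnostics = "diagnostics.csv",
                                forecast = "forecast.csv",
                                manifest = "manifest.json"))
  names(paths) <- c("model", "diagnostics", "forecast", "manifest")
  model_json(model, paths["model"])
  utils::write.csv(diag$table, paths["diagnostics"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fc, paths["forecast"], row.names = FALSE, quote = FALSE)
  manifest <- list(
    fingerprint = config_fingerprint(config),
    config = unclass(config),
    preprocessing = list(
      adjusted_years = as.integer(adjusted),
      prefix_used = prefix,
      prefix_value = if (prefix) config$prefix_value else NULL),
    model = list(a = model$a, b = model$b,
                 applicability = applicability(model)),
    diagnostics = list(mean_relative_error = diag$mean_relative_error,
                       c_ratio = diag$c_ratio,
                       small_error_probability = diag$small_error_probability,
                       level = diag$level, label = diag$label))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paths["manifest"])
  invisible(list(model = model, diagnostics = diag, forecast = fc,
                 paths = paths))
}
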