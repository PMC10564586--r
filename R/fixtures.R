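#' Packaged national-survey summary data
#'
#' `cnpfs_means()` returns the published mean (and SD) of height, weight,
#' chest circumference and BMI for each sex and age 3-6 at the five
#' national physical-fitness surveillance waves (2000, 2005, 2010, 2014,
#' 2020).  SDs are carried as metadata only; modelling uses the means.
#' `cnpfs_rates()` returns the published overweight and obesity detection
#' rates (percent) by sex for the four counted waves (2000-2014).
#'
#' @return A data frame (`indicator`, `sex`, `age`, `year`, `mean`, `sd`
#'   for means; `indicator`, `sex`, `year`, `rate` for rates).
#' @export
cnpfs_means <- function() {
  utils::read.csv(system.file("extdata", "cnpfs_means.csv",
                              package = "greygrowth"))
}

#' @rdname cnpfs_means
#' @export
cnpfs_rates <- function() {
  utils::read.csv(system.file("extdata", "cnpfs_rates.csv",
                              package = "greygrowth"))
}

#' Published table cells for comparison
#'
#' Long-format transcriptions of the published anthropometry model tables
#' (parameters, fitted 2000-2020, predictions 2025/2030, growth deltas by
#' indicator, sex and age) and of the prevalence table, used by
#' [reproduce_tables()] to flag cell-by-cell matches and known mismatches.
#' Typographic errors in the source tables are carried verbatim and listed
#' by [printed_errata()], not silently corrected.
#'
#' @return A long data frame of printed cells (garbled cells are `NA`).
#' @export
printed_anthropometry <- function() {
  utils::read.csv(system.file("extdata", "printed_anthropometry.csv",
                              package = "greygrowth"))
}

#' @rdname printed_anthropometry
#' @export
printed_prevalence <- function() {
  utils::read.csv(system.file("extdata", "printed_prevalence.csv",
                              package = "greygrowth"))
}

#' @rdname printed_anthropometry
#' @export
printed_errata <- function() {
  data.frame(
    indicator = c("weight", "weight", "height", "height"),
    sex = c("girls", "girls", "girls", "girls"),
    age = c(5L, 6L, 6L, 5L),
    field = c("b", "2015", "pct_d2020_2000", "pct_d2020_2000"),
    printed = c("14.8", "22.5", "0.3.7%", "3.7"),
    note = c(
      "printed grey constant 14.8 is inconsistent with the fitted column (about 18.1)",
      "printed fitted 22.5 for 2015 breaks monotonicity (22.1 follows in 2020)",
      "garbled percent cell; stored as NA",
      "percent sign missing in source; value itself is consistent"))
}
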