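# Typed input tables: country parameters, population projections and observed
# burden. All readers return validated tibbles; the bundled fixtures transcribe
# the published input tables for the eight modelled countries.

table1_columns <- function() {
  c("country",
    paste0("dist_", fracture_types()),
    paste0("rr_", fracture_types()),
    paste0("cost_", fracture_types()),
    "med_cost_annual", "bmd_cost",
    "treatment_rate", "identification_rate", "at_risk_treatment_rate")
}

#' Path to a bundled input fixture
#'
#' @param file One of `"table1_inputs.csv"`, `"table2_population.csv"`,
#'   `"table2_burden.csv"`, or `NULL` to list available fixtures.
#' @return A file path (or a vector of file names if `file` is `NULL`).
#' @export
osteo_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "osteoburden")))
  }
  path <- system.file("extdata", file, package = "osteoburden")
  if (!nzchar(path)) stop("no bundled fixture called ", file, call. = FALSE)
  path
}

#' Read country-level fracture and treatment parameters
#'
#' Reads one row per country: the fracture-type distribution (fractions over
#' hip / vertebral / non-hip non-vertebral), treatment-mix-weighted relative
#' risks per fracture type, first-year direct fracture costs (2020 euros),
#' annual anti-osteoporosis medication cost per treated woman, the unit cost
#' of a BMD measurement, and the status-quo management rates: population
#' treatment rate, identification rate of those at risk among those assessed,
#' and treatment rate among those identified at risk.
#'
#' Printed fracture-type percentages are rounded integers, so their sum may
#' miss 1 by up to 0.02; shares are renormalised proportionally to sum to
#' exactly 1 and the raw sum is kept in `dist_renorm`.
#'
#' @param path CSV file with the documented columns; defaults to the bundled
#'   transcription of the published country inputs.
#' @return A tibble with one validated row per country.
#' @export
#' @examples
#' read_country_params()
read_country_params <- function(path = osteo_example("table1_inputs.csv")) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  validate_country_params(raw)
}

#' Validate (and renormalise) a country-parameter table
#'
#' @param raw A data frame with the columns documented in
#'   [read_country_params()].
#' @return The validated tibble, with fracture-type shares renormalised to sum
#'   to 1 and the pre-normalisation sum recorded in `dist_renorm`.
#' @export
validate_country_params <- function(raw) {
  raw <- tibble::as_tibble(raw)
  missing <- setdiff(table1_columns(), names(raw))
  if (length(missing) > 0) {
    stop("country parameter table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$country)) {
    stop("duplicated country code(s) in parameter table", call. = FALSE)
  }
  ft <- fracture_types()
  for (col in c(paste0("dist_", ft), "treatment_rate",
                "identification_rate", "at_risk_treatment_rate")) {
    check_fraction(raw[[col]], col, where = raw$country)
  }
  for (col in paste0("rr_", ft)) check_rr(raw[[col]], col, where = raw$country)
  for (col in c(paste0("cost_", ft), "med_cost_annual", "bmd_cost")) {
    check_nonneg(raw[[col]], col, where = raw$country)
  }
  dist_sum <- raw$dist_hip + raw$dist_vertebral + raw$dist_nhnv
  off <- abs(dist_sum - 1) > 0.02
  if (any(off)) {
    stop(sprintf(
      "fracture-type distribution for %s sums to %.3f (must be 1 +/- 0.02)",
      raw$country[off][1], dist_sum[off][1]), call. = FALSE)
  }
  dplyr::mutate(
    raw,
    dplyr::across(dplyr::all_of(paste0("dist_", ft)), ~ .x / dist_sum),
    dist_renorm = dist_sum
  )
}

#' Read population projections
#'
#' Number of women aged 70 years and older per country and snapshot year.
#' The grid must be complete: every country present for every year observed
#' in the file.
#'
#' @param path CSV with columns `country`, `year`, `population`; defaults to
#'   the bundled projections for the eight modelled countries at the five
#'   snapshot years 2020, 2025, 2030, 2035, 2040.
#' @return A tibble `country`, `year`, `population`.
#' @export
read_population <- function(path = osteo_example("table2_population.csv")) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  validate_population(raw)
}

#' @rdname read_population
#' @param raw A data frame with columns `country`, `year`, `population`.
#' @export
validate_population <- function(raw) {
  raw <- tibble::as_tibble(raw)
  missing <- setdiff(c("country", "year", "population"), names(raw))
  if (length(missing) > 0) {
    stop("population table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(raw$population) | raw$population <= 0 |
    raw$population != round(raw$population)
  if (any(bad)) {
    stop("population must be a positive integer count (",
         raw$country[bad][1], " ", raw$year[bad][1], ")", call. = FALSE)
  }
  grid <- tidyr::expand_grid(country = unique(raw$country),
                             year = sort(unique(raw$year)))
  gaps <- dplyr::anti_join(grid, raw, by = c("country", "year"))
  if (nrow(gaps) > 0) {
    stop("population grid is incomplete; missing: ",
         paste(paste(gaps$country, gaps$year), collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(raw, .data$country, .data$year)
}

#' Read observed status-quo burden (calibration targets)
#'
#' Observed annual fracture counts and total direct costs of care per country
#' and year, used as calibration targets and as the reference fixture. The
#' per-100,000 columns are the published display values (fractures rounded to
#' integers; cost, in EUR millions, to one decimal) retained for comparison.
#'
#' @param path CSV with columns `country`, `year`, `fractures`,
#'   `fractures_per_100k`, `cost_millions`, `cost_per_100k`.
#' @return A validated tibble.
#' @export
read_burden_targets <- function(path = osteo_example("table2_burden.csv")) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  raw <- tibble::as_tibble(raw)
  missing <- setdiff(c("country", "year", "fractures", "cost_millions"),
                     names(raw))
  if (length(missing) > 0) {
    stop("burden table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_nonneg(raw$fractures, "fractures", raw$country)
  check_nonneg(raw$cost_millions, "cost_millions", raw$country)
  dplyr::arrange(raw, .data$country, .data$year)
}

#' Global status-quo management assumptions
#'
#' Under the status quo a fixed fraction of women are assessed for fracture
#' risk and a fixed fraction of treated women adhere to their medication,
#' identical across countries: 25% assessment and 40% adherence by default.
#'
#' @param assessment_rate Fraction of women receiving a fracture-risk
#'   assessment (BMD measurement) per year.
#' @param adherence_rate Fraction of treated women who adhere to
#'   anti-osteoporosis medication (non-adherent women receive no modelled
#'   treatment benefit).
#' @return A one-row tibble.
#' @export
global_assumptions <- function(assessment_rate = 0.25, adherence_rate = 0.40) {
  check_fraction(assessment_rate, "assessment_rate")
  check_fraction(adherence_rate, "adherence_rate")
  tibble::tibble(assessment_rate = assessment_rate,
                 adherence_rate = adherence_rate)
}

#' Snapshot years of the analysis
#'
#' The model is cross-sectional per year; no interpolation is performed
#' between snapshots.
#'
#' @return Integer vector of the five analysed years.
#' @export
snapshot_years <- function() {
  c(2020L, 2025L, 2030L, 2035L, 2040L)
}

#' Adjust an amount for consumer-price inflation
#'
#' Simple CPI rescaling utility. Model inputs are assumed to be pre-adjusted
#' to 2020 euros, so this is provided for preparing new inputs and is never
#' applied by default.
#'
#' @param amount Numeric amount(s).
#' @param cpi_from CPI index in the amount's original year.
#' @param cpi_to CPI index in the target year.
#' @return `amount * cpi_to / cpi_from`.
#' @export
cpi_adjust <- function(amount, cpi_from, cpi_to) {
  if (any(!is.finite(cpi_from) | cpi_from <= 0) ||
      any(!is.finite(cpi_to) | cpi_to <= 0)) {
    stop("CPI indices must be positive", call. = FALSE)
  }
  amount * cpi_to / cpi_from
}

#' Write model input tables
#'
#' Writers matching [read_country_params()] and [read_population()]; a
#' write-then-read round trip reproduces the table exactly. Note the writer
#' stores the (renormalised) shares as read back.
#'
#' @param x Tibble to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_country_params <- function(x, path) {
  readr::write_csv(dplyr::select(x, -dplyr::any_of("dist_renorm")), path)
  invisible(path)
}

#' @rdname write_country_params
#' @export
write_population <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
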