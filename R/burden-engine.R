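# Burden engine: fracture counts and direct costs of care from population
# sizes and per-type risks; per-100,000 normalisation; net benefit versus the
# status quo. All arithmetic is carried out on real-valued expectations; the
# model is a cross-sectional cohort, so counts are expected values rounded
# only at reporting boundaries.

#' Annual expected fracture counts
#'
#' @param n Population of women aged 70+ (positive).
#' @param risk Named per-type annual fracture probabilities (`hip`,
#'   `vertebral`, `nhnv`), each in `[0, 1]`.
#' @return One-row tibble with per-type counts (rounded half away from zero)
#'   and their `total`.
#' @export
#' @examples
#' annual_fractures(100000, c(hip = 0.01, vertebral = 0.005, nhnv = 0.03))
annual_fractures <- function(n, risk) {
  stopifnot(n > 0)
  risk <- risk[fracture_types()]
  check_fraction(risk, "risk")
  counts <- round_half_up(n * risk)
  out <- tibble::as_tibble(as.list(counts))
  out$total <- sum(counts)
  out
}

#' Annual direct costs of care
#'
#' Three components, reported in EUR millions (2020 euros):
#' * fracture care: per-type counts times first-year direct unit costs
#'   (times an optional calibration `cost_scale` on this component only);
#' * medication: population times treatment rate times annual medication
#'   cost — charged for all treated women regardless of adherence unless
#'   `med_scale_by_adherence` is set;
#' * risk assessment: population times assessment rate times the unit cost
#'   of a BMD measurement, incurred annually by the assessed share.
#'
#' @param counts Named per-type fracture counts.
#' @param params_row One country's parameter row ([read_country_params()]).
#' @param rates One-row tibble of management rates.
#' @param n Population size.
#' @param cost_scale Multiplicative calibration factor on the fracture
#'   component (default 1).
#' @param med_scale_by_adherence If `TRUE`, medication costs accrue only for
#'   adherent treated women.
#' @return One-row tibble `cost_fracture`, `cost_medication`,
#'   `cost_assessment`, `cost_total` (EUR millions).
#' @export
annual_costs <- function(counts, params_row, rates, n, cost_scale = 1,
                         med_scale_by_adherence = FALSE) {
  stopifnot(nrow(params_row) == 1, n > 0)
  counts <- counts[fracture_types()]
  unit <- c(params_row$cost_hip, params_row$cost_vertebral,
            params_row$cost_nhnv)
  adh <- if (med_scale_by_adherence) rates$adherence_rate else 1
  fracture <- sum(counts * unit) * cost_scale / 1e6
  medication <- n * rates$treatment_rate * adh *
    params_row$med_cost_annual / 1e6
  assessment <- n * rates$assessment_rate * params_row$bmd_cost / 1e6
  tibble::tibble(cost_fracture = fracture,
                 cost_medication = medication,
                 cost_assessment = assessment,
                 cost_total = fracture + medication + assessment)
}

#' Normalise a value per 100,000 women
#'
#' @param value Numeric value(s) (fracture counts or costs).
#' @param n Population of women aged 70+ (positive).
#' @param digits Optional rounding (half away from zero) applied to the rate:
#'   published tables show fracture rates to the integer (`digits = 0`) and
#'   cost rates to one decimal (`digits = 1`). Default: no rounding.
#' @return `value / n * 1e5`, optionally rounded.
#' @export
#' @examples
#' per_100k(48700, 909965, digits = 0)
per_100k <- function(value, n, digits = NULL) {
  if (any(!is.finite(n) | n <= 0)) {
    stop("`n` must be a positive population size", call. = FALSE)
  }
  out <- value / n * 1e5
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Net benefit of an intervention versus the status quo
#'
#' Signed differences, intervention minus status quo, in annual fractures and
#' total costs of care, with relative percentages (100 * delta / status-quo
#' value). Negative values are reductions (fractures prevented, costs saved).
#'
#' @param status_quo,intervention Burden tibbles covering the same keys
#'   (`country`/`year`, or `year` only for aggregates), with columns
#'   `fractures` and `cost_total`.
#' @return A tibble keyed like the inputs with `delta_fractures`,
#'   `pct_fractures`, `delta_cost`, `pct_cost` (intervention scenario label
#'   retained if present).
#' @export
net_benefit <- function(status_quo, intervention) {
  keys <- intersect(c("country", "year"), names(status_quo))
  keys <- intersect(keys, names(intervention))
  if (length(keys) == 0) stop("no shared keys to match on", call. = FALSE)
  sq <- dplyr::select(status_quo, dplyr::all_of(keys),
                      sq_fractures = "fractures", sq_cost = "cost_total")
  iv <- dplyr::select(intervention, dplyr::any_of(c(keys, "scenario")),
                      fractures = "fractures", cost_total = "cost_total")
  if (nrow(sq) != nrow(iv)) {
    stop("mismatched keys: status quo and intervention cover different ",
         "country-years", call. = FALSE)
  }
  joined <- dplyr::inner_join(iv, sq, by = keys)
  if (nrow(joined) != nrow(sq)) {
    stop("mismatched keys: status quo and intervention cover different ",
         "country-years", call. = FALSE)
  }
  dplyr::transmute(
    joined,
    dplyr::across(dplyr::any_of(c("scenario", keys))),
    delta_fractures = .data$fractures - .data$sq_fractures,
    pct_fractures = 100 * .data$delta_fractures / .data$sq_fractures,
    delta_cost = .data$cost_total - .data$sq_cost,
    pct_cost = 100 * .data$delta_cost / .data$sq_cost
  )
}

#' Aggregate country-level burden estimates
#'
#' Sums counts and cost components over countries (per scenario and year, as
#' available) and recomputes per-100,000 rates from the summed population.
#'
#' @param estimates Burden tibble with one row per country (and year /
#'   scenario), as produced by [estimate_burden()].
#' @param countries Countries that must be present in every group; defaults
#'   to all countries appearing in `estimates`. A missing country is an
#'   error.
#' @return The aggregated tibble (no `country` column).
#' @export
aggregate_burden <- function(estimates,
                             countries = unique(estimates$country)) {
  grp <- intersect(c("scenario", "year"), names(estimates))
  out <- estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp)))
  miss <- out |>
    dplyr::summarise(
      missing = paste(setdiff(countries, .data$country), collapse = ", "),
      .groups = "drop") |>
    dplyr::filter(.data$missing != "")
  if (nrow(miss) > 0) {
    stop("aggregate is missing country estimate(s): ", miss$missing[1],
         call. = FALSE)
  }
  out |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of(c(
        "population", paste0("fx_", fracture_types()), "fractures",
        "cost_fracture", "cost_medication", "cost_assessment", "cost_total")),
        sum),
      .groups = "drop") |>
    dplyr::mutate(
      fractures_per_100k = per_100k(.data$fractures, .data$population),
      cost_per_100k = per_100k(.data$cost_total, .data$population))
}
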