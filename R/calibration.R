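# Calibration: back-solve the baseline-stratum per-type risks so that the
# status-quo model reproduces observed burden, and a cost-scale factor so the
# modelled cost total matches the observed total. The population-average risk
# is linear in the baseline rate (the stratification only mixes fixed
# multipliers), so the inversion is closed-form.

#' Calibrate baseline per-type risks to an observed fracture rate
#'
#' The observed all-type fracture rate is split across fracture types in
#' proportion to the country's fracture-type distribution; each per-type
#' target is then divided by the status-quo mixture factor (strata x
#' treatment states) to give the baseline-stratum annual probability.
#' Because the mixture factor does not depend on the baseline rate, the
#' status-quo model reproduces the target exactly (up to floating point).
#'
#' @param fractures_per_100k Observed annual fractures per 100,000 women 70+.
#' @param params_row One country's parameter row.
#' @param assumptions Global assumptions ([global_assumptions()]).
#' @param at_risk_share,at_risk_multiplier Stratification constants, see
#'   [risk_profile()].
#' @param rates Optional management rates to calibrate against; defaults to
#'   the country's status quo.
#' @return A [risk_profile()] whose status-quo population risk reproduces the
#'   target.
#' @export
#' @examples
#' params <- read_country_params()
#' calibrate_baseline(5352, params[params$country == "BE", ])
calibrate_baseline <- function(fractures_per_100k, params_row,
                               assumptions = global_assumptions(),
                               at_risk_share = 0.30, at_risk_multiplier = 4.0,
                               rates = NULL) {
  stopifnot(nrow(params_row) == 1)
  if (!is.finite(fractures_per_100k) || fractures_per_100k <= 0) {
    stop("`fractures_per_100k` must be positive", call. = FALSE)
  }
  if (is.null(rates)) {
    rates <- management_rates(assumptions$assessment_rate,
                              params_row$treatment_rate,
                              assumptions$adherence_rate)
  }
  dist <- c(hip = params_row$dist_hip, vertebral = params_row$dist_vertebral,
            nhnv = params_row$dist_nhnv)
  rr <- c(hip = params_row$rr_hip, vertebral = params_row$rr_vertebral,
          nhnv = params_row$rr_nhnv)
  target <- fractures_per_100k / 1e5 * dist
  fac <- risk_mixture_factor(rr, rates, at_risk_share, at_risk_multiplier)
  base <- target / fac
  if (any(base * at_risk_multiplier > 1)) {
    bad <- names(base)[base * at_risk_multiplier > 1][1]
    stop(sprintf(
      "infeasible target: calibrated %s probability in the at-risk stratum ",
      bad), sprintf("would be %.3f > 1 (target %.0f/100k, multiplier %.1f)",
                    (base * at_risk_multiplier)[bad], fractures_per_100k,
                    at_risk_multiplier), call. = FALSE)
  }
  risk_profile(base, at_risk_share, at_risk_multiplier)
}

#' Cost-scale calibration factor
#'
#' Multiplicative factor aligning a modelled cost with an observed target.
#' In the pipeline it is applied to the fracture-cost component only
#' (medication and assessment components are structural, computed from
#' printed unit costs and rates), so the caller passes the observed total
#' net of the structural components as `target` and the modelled fracture
#' component as `modelled`.
#'
#' @param target Observed cost (any consistent unit).
#' @param modelled Modelled cost in the same unit; must be positive.
#' @return `target / modelled`.
#' @export
#' @examples
#' calibrate_cost_scale(292, 313.1)
calibrate_cost_scale <- function(target, modelled) {
  if (any(!is.finite(target) | target <= 0) ||
      any(!is.finite(modelled) | modelled <= 0)) {
    stop("costs must be positive to calibrate a scale factor", call. = FALSE)
  }
  target / modelled
}

#' Calibrate the full model to observed burden
#'
#' For every (country, year) in `targets`, back-solves the baseline per-type
#' risks from the observed fracture count and a fracture-cost scale factor
#' from the observed cost total (components per [annual_costs()]). The
#' fracture target is taken from the observed *count* (so counts round-trip
#' exactly and per-100,000 display values agree at their printed precision).
#'
#' @param params Country parameters ([read_country_params()]).
#' @param population Population projections ([read_population()]).
#' @param targets Observed burden ([read_burden_targets()]); `cost_millions`
#'   may be `NA` to skip cost calibration for a row (scale 1).
#' @param assumptions Global assumptions.
#' @param at_risk_share,at_risk_multiplier Stratification constants.
#' @param med_scale_by_adherence Passed through to the cost model.
#' @return An object of class `burden_model` bundling inputs, solved baseline
#'   rates (`base_rates`: country, year, type, base_rate), cost scale factors
#'   (`cost_scale`), and settings.
#' @export
#' @examples
#' mod <- calibrate_model(read_country_params(), read_population(),
#'                        read_burden_targets())
#' mod
calibrate_model <- function(params, population, targets,
                            assumptions = global_assumptions(),
                            at_risk_share = 0.30, at_risk_multiplier = 4.0,
                            med_scale_by_adherence = FALSE) {
  if (!"cost_millions" %in% names(targets)) targets$cost_millions <- NA_real_
  keys <- targets |>
    dplyr::select("country", "year", "fractures", "cost_millions") |>
    dplyr::inner_join(population, by = c("country", "year"))
  if (nrow(keys) < nrow(targets)) {
    stop("targets reference (country, year) pairs absent from the ",
         "population projection", call. = FALSE)
  }
  rows <- purrr::pmap(keys, function(country, year, fractures, cost_millions,
                                     population, ...) {
    prow <- params[params$country == country, ]
    if (nrow(prow) != 1) {
      stop("no parameter row for country ", country, call. = FALSE)
    }
    rates <- management_rates(assumptions$assessment_rate,
                              prow$treatment_rate,
                              assumptions$adherence_rate)
    profile <- calibrate_baseline(per_100k(fractures, population), prow,
                                  assumptions, at_risk_share,
                                  at_risk_multiplier, rates = rates)
    rr <- c(hip = prow$rr_hip, vertebral = prow$rr_vertebral,
            nhnv = prow$rr_nhnv)
    risk <- population_risk(profile, rates, rr)
    counts <- population * risk
    cost <- annual_costs(counts, prow, rates, population,
                         med_scale_by_adherence = med_scale_by_adherence)
    scale <- 1
    if (!is.null(cost_millions) && is.finite(cost_millions)) {
      structural <- cost$cost_medication + cost$cost_assessment
      if (cost_millions <= structural) {
        stop(sprintf(
          "infeasible cost target for %s %d: observed total %.1f below ",
          country, year, cost_millions),
          sprintf("structural medication + assessment costs %.1f",
                  structural), call. = FALSE)
      }
      scale <- calibrate_cost_scale(cost_millions - structural,
                                    cost$cost_fracture)
    }
    list(
      base = tibble::tibble(country = country, year = year,
                            type = fracture_types(),
                            base_rate = unname(profile$base_rates)),
      scale = tibble::tibble(country = country, year = year,
                             cost_scale = scale,
                             modelled_fracture_cost = cost$cost_fracture,
                             residual_per_100k = per_100k(
                               population * sum(risk) - fractures,
                               population))
    )
  })
  structure(list(
    base_rates = dplyr::bind_rows(purrr::map(rows, "base")),
    cost_scale = dplyr::bind_rows(purrr::map(rows, "scale")),
    params = params, population = population, targets = targets,
    assumptions = assumptions, at_risk_share = at_risk_share,
    at_risk_multiplier = at_risk_multiplier,
    med_scale_by_adherence = med_scale_by_adherence
  ), class = "burden_model")
}

#' @export
print.burden_model <- function(x, ...) {
  cat("<burden_model>\n")
  cat(sprintf("  %d countries x %d years calibrated\n",
              length(unique(x$base_rates$country)),
              length(unique(x$base_rates$year))))
  cat(sprintf("  at-risk share %.2f, multiplier %.2f\n",
              x$at_risk_share, x$at_risk_multiplier))
  cat(sprintf("  cost scale factors: %.3f - %.3f\n",
              min(x$cost_scale$cost_scale), max(x$cost_scale$cost_scale)))
  invisible(x)
}

#' Calibration report
#'
#' One row per (country, year): solved baseline rates (wide, per type),
#' round-trip residual in fractures per 100,000, and the fracture-cost scale
#' factor with its deviation from 1.
#'
#' @param model A [calibrate_model()] fit.
#' @return A tibble.
#' @export
calibration_report <- function(model) {
  stopifnot(inherits(model, "burden_model"))
  wide <- tidyr::pivot_wider(model$base_rates, names_from = "type",
                             values_from = "base_rate",
                             names_prefix = "base_")
  dplyr::left_join(wide, model$cost_scale, by = c("country", "year")) |>
    dplyr::mutate(cost_scale_deviation = .data$cost_scale - 1)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibrated burden model
#'
#' @param x A `burden_model`.
#' @param ... Unused.
#' @return Long tibble of solved baseline rates: `country`, `year`, `type`,
#'   `base_rate`, plus the country's cost scale factor.
#' @export
tidy.burden_model <- function(x, ...) {
  dplyr::left_join(x$base_rates, x$cost_scale[, c("country", "year",
                                                  "cost_scale")],
                   by = c("country", "year"))
}

#' Glance at a calibrated burden model
#'
#' @param x A `burden_model`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, largest absolute round-trip residual
#'   (fractures per 100,000) and the cost scale range.
#' @export
glance.burden_model <- function(x, ...) {
  tibble::tibble(
    n_countries = length(unique(x$base_rates$country)),
    n_years = length(unique(x$base_rates$year)),
    at_risk_share = x$at_risk_share,
    at_risk_multiplier = x$at_risk_multiplier,
    max_abs_residual_per_100k = max(abs(x$cost_scale$residual_per_100k)),
    cost_scale_min = min(x$cost_scale$cost_scale),
    cost_scale_max = max(x$cost_scale$cost_scale)
  )
}
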