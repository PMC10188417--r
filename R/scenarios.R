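# Scenario pipeline and reporting: run the calibrated model under a grid of
# interventions, aggregate, difference against the status quo, and render
# tables mirroring the published layout.

#' Burden estimate for one scenario
#'
#' Applies the scenario's management rates to every calibrated (country,
#' year), converts per-type population risks to expected fracture counts and
#' costs, and normalises per 100,000. Counts are expected values; `fractures`
#' is the rounded total (per-type expectations are kept unrounded in the
#' `fx_*` columns).
#'
#' @param model A [calibrate_model()] fit.
#' @param spec A one-row [intervention_spec()].
#' @param nonadherent_efficacy Fraction of treatment efficacy retained by
#'   non-adherent treated women (default 0).
#' @return A tibble with one row per country-year: scenario, population,
#'   per-type expected counts, rounded total fractures, cost components and
#'   totals (EUR millions), and per-100k rates (unrounded).
#' @export
#' @examples
#' mod <- calibrate_model(read_country_params(), read_population(),
#'                        read_burden_targets())
#' estimate_burden(mod, intervention_spec("adherence", 0.5))
estimate_burden <- function(model, spec = intervention_spec("status_quo"),
                            nonadherent_efficacy = 0) {
  stopifnot(inherits(model, "burden_model"))
  rates <- apply_intervention(model$params, spec, model$assumptions)
  base_wide <- tidyr::pivot_wider(model$base_rates, names_from = "type",
                                  values_from = "base_rate",
                                  names_prefix = "base_")
  df <- base_wide |>
    dplyr::inner_join(model$population, by = c("country", "year")) |>
    dplyr::inner_join(model$params, by = "country") |>
    dplyr::inner_join(rates, by = "country", suffix = c("_sq", "")) |>
    dplyr::inner_join(model$cost_scale[, c("country", "year", "cost_scale")],
                      by = c("country", "year"))
  s <- model$at_risk_share
  m <- model$at_risk_multiplier
  rates_df <- tibble::tibble(treatment_rate = df$treatment_rate,
                             adherence_rate = df$adherence_rate)
  for (ft in fracture_types()) {
    fac <- risk_mixture_factor(df[[paste0("rr_", ft)]], rates_df, s, m,
                               nonadherent_efficacy)
    p <- cap_probabilities(df[[paste0("base_", ft)]] * fac, warn = FALSE)
    df[[paste0("fx_", ft)]] <- df$population * p
  }
  fx_total <- df$fx_hip + df$fx_vertebral + df$fx_nhnv
  unit_cost <- as.matrix(df[, paste0("cost_", fracture_types())])
  counts <- as.matrix(df[, paste0("fx_", fracture_types())])
  adh <- if (model$med_scale_by_adherence) df$adherence_rate else 1
  cost_fracture <- rowSums(counts * unit_cost) * df$cost_scale / 1e6
  cost_medication <- df$population * df$treatment_rate * adh *
    df$med_cost_annual / 1e6
  cost_assessment <- df$population * df$assessment_rate * df$bmd_cost / 1e6
  tibble::tibble(
    scenario = spec$label,
    country = df$country,
    year = df$year,
    population = df$population,
    fx_hip = df$fx_hip, fx_vertebral = df$fx_vertebral, fx_nhnv = df$fx_nhnv,
    fractures = round_half_up(fx_total),
    fractures_per_100k = per_100k(fx_total, df$population),
    cost_fracture = cost_fracture,
    cost_medication = cost_medication,
    cost_assessment = cost_assessment,
    cost_total = cost_fracture + cost_medication + cost_assessment,
    cost_per_100k = per_100k(cost_fracture + cost_medication +
                               cost_assessment, df$population),
    assessment_rate = df$assessment_rate,
    treatment_rate = df$treatment_rate,
    adherence_rate = df$adherence_rate
  )
}

#' Run a scenario grid
#'
#' Runs the calibrated model under every scenario in the grid (the status quo
#' is added if absent; it may appear only once), aggregates across countries
#' per year, and computes net benefits versus the status quo at country and
#' aggregate level.
#'
#' @param model A [calibrate_model()] fit.
#' @param scenarios Scenario grid, e.g. [default_scenarios()] or a tibble of
#'   [intervention_spec()] rows. An empty grid (zero rows) runs the status
#'   quo only.
#' @param nonadherent_efficacy See [estimate_burden()].
#' @return An object of class `scenario_result` with elements `burden`
#'   (country level), `aggregate` (eight-country totals per year),
#'   `net_benefit` (aggregate level), `net_benefit_country`, `scenarios`.
#' @export
#' @examples
#' mod <- calibrate_model(read_country_params(), read_population(),
#'                        read_burden_targets())
#' res <- run_scenarios(mod, default_scenarios())
#' glance(res)
run_scenarios <- function(model, scenarios = default_scenarios(),
                          nonadherent_efficacy = 0) {
  stopifnot(inherits(model, "burden_model"))
  if (nrow(scenarios) == 0 || !"status_quo" %in% scenarios$label) {
    scenarios <- dplyr::bind_rows(intervention_spec("status_quo"), scenarios)
  }
  if (sum(scenarios$label == "status_quo") > 1) {
    stop("the status quo must appear exactly once in the scenario grid",
         call. = FALSE)
  }
  if (anyDuplicated(scenarios$label)) {
    stop("duplicated scenario label(s)", call. = FALSE)
  }
  burden <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    estimate_burden(model, scenarios[i, ], nonadherent_efficacy)
  }) |> dplyr::bind_rows()
  aggregate <- aggregate_burden(burden,
                                countries = unique(model$params$country))
  sq_c <- dplyr::filter(burden, .data$scenario == "status_quo")
  sq_a <- dplyr::filter(aggregate, .data$scenario == "status_quo")
  iv_c <- dplyr::filter(burden, .data$scenario != "status_quo")
  nb_country <- if (nrow(iv_c) > 0) {
    iv_c |>
      dplyr::group_split(.data$scenario) |>
      purrr::map(~ net_benefit(sq_c, .x)) |>
      dplyr::bind_rows()
  } else tibble::tibble()
  iv_a <- dplyr::filter(aggregate, .data$scenario != "status_quo")
  nb_total <- if (nrow(iv_a) > 0) {
    iv_a |>
      dplyr::group_split(.data$scenario) |>
      purrr::map(~ net_benefit(sq_a, .x)) |>
      dplyr::bind_rows()
  } else tibble::tibble()
  structure(list(burden = burden, aggregate = aggregate,
                 net_benefit = nb_total, net_benefit_country = nb_country,
                 scenarios = scenarios, model = model),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>\n")
  cat(sprintf("  %d scenario(s) x %d countries x %d years\n",
              nrow(x$scenarios), length(unique(x$burden$country)),
              length(unique(x$burden$year))))
  sq <- dplyr::filter(x$aggregate, .data$scenario == "status_quo")
  cat(sprintf("  status quo %d: %s fractures, EUR %sM\n", min(sq$year),
              format(sq$fractures[which.min(sq$year)], big.mark = ","),
              format(round(sq$cost_total[which.min(sq$year)]),
                     big.mark = ",")))
  invisible(x)
}

#' Tidy a scenario result
#'
#' @param x A `scenario_result`.
#' @param level `"country"` (default), `"aggregate"` or `"net_benefit"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.scenario_result <- function(x, level = c("country", "aggregate",
                                              "net_benefit"), ...) {
  level <- match.arg(level)
  switch(level, country = x$burden, aggregate = x$aggregate,
         net_benefit = x$net_benefit)
}

#' Glance at a scenario result
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return One row per scenario: totals in the first and last modelled year
#'   and net benefit in the last year.
#' @export
glance.scenario_result <- function(x, ...) {
  y0 <- min(x$aggregate$year)
  y1 <- max(x$aggregate$year)
  out <- x$aggregate |>
    dplyr::filter(.data$year %in% c(y0, y1)) |>
    dplyr::select("scenario", "year", "fractures", "cost_total") |>
    tidyr::pivot_wider(names_from = "year",
                       values_from = c("fractures", "cost_total"))
  if (nrow(x$net_benefit) > 0) {
    nb <- x$net_benefit |>
      dplyr::filter(.data$year == y1) |>
      dplyr::select("scenario", "delta_fractures", "pct_fractures",
                    "delta_cost", "pct_cost")
    out <- dplyr::left_join(out, nb, by = "scenario")
  }
  out
}

# Rendering -------------------------------------------------------------------

fmt_count <- function(x) format(round_half_up(x), big.mark = ",",
                                scientific = FALSE, trim = TRUE)

# "- 217,843 (- 17.6%)" with a typographic minus, as in the published table
fmt_delta <- function(delta, pct, currency = FALSE) {
  sgn <- ifelse(delta < 0, "− ", ifelse(delta > 0, "+ ", ""))
  sgn_p <- ifelse(pct < 0, "− ", ifelse(pct > 0, "+ ", ""))
  val <- fmt_count(abs(delta))
  if (currency) val <- paste0("€", val)
  sprintf("%s%s (%s%.1f%%)", sgn, val, sgn_p, abs(pct))
}

md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Render scenario results as Markdown tables
#'
#' Produces a status-quo burden table (absolute values with per-100,000
#' sub-rows: fracture rates to the integer, cost rates to one decimal) and,
#' when intervention scenarios are present, a net-benefit table formatted as
#' "delta (relative %)" with minus signs as published. A status-quo-only
#' result renders no net-benefit section.
#'
#' @param result A [run_scenarios()] result with at least one scenario.
#' @return A single Markdown string (invisibly printable with `cat()`).
#' @export
render_tables <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  if (nrow(result$aggregate) == 0) stop("empty result", call. = FALSE)
  years <- sort(unique(result$aggregate$year))
  sq <- result$burden |>
    dplyr::filter(.data$scenario == "status_quo")
  sq_a <- result$aggregate |>
    dplyr::filter(.data$scenario == "status_quo") |>
    dplyr::mutate(country = "Total")
  blocks <- list()
  mk_rows <- function(df, value, rate, rate_digits) {
    abs_row <- df |>
      dplyr::mutate(v = fmt_count(.data[[value]])) |>
      dplyr::select("country", "year", "v") |>
      tidyr::pivot_wider(names_from = "year", values_from = "v")
    rate_row <- df |>
      dplyr::mutate(v = format(round_half_up(.data[[rate]], rate_digits),
                               nsmall = rate_digits, trim = TRUE),
                    country = paste0(.data$country, ", per 100,000")) |>
      dplyr::select("country", "year", "v") |>
      tidyr::pivot_wider(names_from = "year", values_from = "v")
    interleaved <- vector("list", 2 * nrow(abs_row))
    interleaved[seq(1, by = 2, length.out = nrow(abs_row))] <-
      split(abs_row, seq_len(nrow(abs_row)))
    interleaved[seq(2, by = 2, length.out = nrow(rate_row))] <-
      split(rate_row, seq_len(nrow(rate_row)))
    dplyr::bind_rows(interleaved)
  }
  both <- dplyr::bind_rows(sq, sq_a)
  blocks$fractures <- paste0(
    "## Annual numbers of osteoporotic fractures (status quo)\n\n",
    md_table(mk_rows(both, "fractures", "fractures_per_100k", 0)))
  blocks$costs <- paste0(
    "## Annual costs of care, EUR millions (status quo)\n\n",
    md_table(mk_rows(both, "cost_total", "cost_per_100k", 1)))
  if (nrow(result$net_benefit) > 0) {
    nb <- result$net_benefit |>
      dplyr::mutate(
        Fractures = fmt_delta(.data$delta_fractures, .data$pct_fractures),
        Costs = fmt_delta(.data$delta_cost, .data$pct_cost,
                          currency = TRUE)) |>
      dplyr::select("scenario", "year", "Fractures", "Costs") |>
      tidyr::pivot_longer(c("Fractures", "Costs"), names_to = "outcome") |>
      tidyr::pivot_wider(names_from = "year", values_from = "value") |>
      dplyr::arrange(.data$scenario, .data$outcome)
    blocks$nb <- paste0(
      "## Net benefits from status quo (relative percentage reduction)\n\n",
      md_table(nb))
  }
  paste(unlist(blocks), collapse = "\n\n")
}

#' Plot projected burden by scenario
#'
#' Line chart of annual eight-country totals (fractures and costs of care)
#' against snapshot year, one line per scenario.
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_result <- function(object, ...) {
  df <- object$aggregate |>
    dplyr::transmute(.data$scenario, .data$year,
                     `Fractures (thousands)` = .data$fractures / 1e3,
                     `Costs of care (EUR millions)` = .data$cost_total) |>
    tidyr::pivot_longer(-c("scenario", "year"), names_to = "measure")
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$value,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "Scenario",
                  title = "Projected annual burden, eight-country total") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.scenario_result
#' @param result A `scenario_result`.
#' @export
plot_burden_projection <- function(result) {
  autoplot(result)
}
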