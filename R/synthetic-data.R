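# Synthetic-data generator: country parameter sets, population projections
# and calibration targets with the statistical structure the analysis
# assumes, plus an individual-level microsimulation oracle for the cohort
# equations. Synthetic fixtures satisfy every input validation and use the
# same schemas as the bundled tables, so they are interchangeable with them.

#' Specification for synthetic country generation
#'
#' Ranges default to the spread observed across the eight modelled European
#' countries (fracture-type mixes around 1/5 hip, 1/7 vertebral; treatment
#' relative risks strongest for vertebral fracture; unit costs spanning the
#' Central-European to Swiss range), so that a default draw is a plausible
#' "ninth country". The seed fully determines the output.
#'
#' @param seed Integer seed for the single pseudo-random stream.
#' @param n_countries Number of countries to generate.
#' @param dist_hip,dist_vertebral Ranges (low, high) of fracture-type shares;
#'   the non-hip non-vertebral share is the complement.
#' @param rr_hip,rr_vertebral,rr_nhnv Relative-risk ranges in (0, 1].
#' @param cost_hip,cost_vertebral,cost_nhnv First-year fracture cost ranges
#'   (EUR).
#' @param med_cost_annual,bmd_cost Cost ranges (EUR).
#' @param treatment_rate,identification_rate,at_risk_treatment_rate
#'   Management-rate ranges.
#' @param population Range of the base-year population of women 70+.
#' @param growth Range of annual population growth.
#' @param fracture_rate Range of the all-type fracture rate per 100,000.
#' @param years Snapshot years.
#' @return A list of class `synthetic_country_spec`.
#' @export
synthetic_country_spec <- function(
    seed = 1L, n_countries = 8L,
    dist_hip = c(0.15, 0.22), dist_vertebral = c(0.10, 0.16),
    rr_hip = c(0.55, 0.65), rr_vertebral = c(0.40, 0.56),
    rr_nhnv = c(0.70, 0.85),
    cost_hip = c(4500, 20000), cost_vertebral = c(1000, 12000),
    cost_nhnv = c(1900, 12500),
    med_cost_annual = c(30, 500), bmd_cost = c(10, 100),
    treatment_rate = c(0.06, 0.30), identification_rate = c(0.40, 0.80),
    at_risk_treatment_rate = c(0.09, 0.50),
    population = c(250000, 8000000), growth = c(0.01, 0.03),
    fracture_rate = c(2800, 8000), years = snapshot_years()) {
  spec <- list(seed = as.integer(seed), n_countries = as.integer(n_countries),
               dist_hip = dist_hip, dist_vertebral = dist_vertebral,
               rr_hip = rr_hip, rr_vertebral = rr_vertebral,
               rr_nhnv = rr_nhnv, cost_hip = cost_hip,
               cost_vertebral = cost_vertebral, cost_nhnv = cost_nhnv,
               med_cost_annual = med_cost_annual, bmd_cost = bmd_cost,
               treatment_rate = treatment_rate,
               identification_rate = identification_rate,
               at_risk_treatment_rate = at_risk_treatment_rate,
               population = population, growth = growth,
               fracture_rate = fracture_rate, years = years)
  ranges <- spec[setdiff(names(spec), c("seed", "n_countries", "years"))]
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] < 0) {
      stop("invalid range for `", nm, "`", call. = FALSE)
    }
  }
  for (nm in c("dist_hip", "dist_vertebral", "treatment_rate",
               "identification_rate", "at_risk_treatment_rate")) {
    if (spec[[nm]][2] > 1) stop("`", nm, "` range must lie in [0, 1]",
                                call. = FALSE)
  }
  for (nm in c("rr_hip", "rr_vertebral", "rr_nhnv")) {
    if (spec[[nm]][1] <= 0 || spec[[nm]][2] > 1) {
      stop("`", nm, "` range must lie in (0, 1]", call. = FALSE)
    }
  }
  if (spec$n_countries < 1) stop("`n_countries` must be >= 1", call. = FALSE)
  class(spec) <- "synthetic_country_spec"
  spec
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate synthetic countries, populations and calibration targets
#'
#' Draws country parameters uniformly within the specification's ranges, a
#' base-year population (log-uniform) with constant annual growth, an
#' all-type fracture rate per country (jittered across years by +/-5%), and a
#' cost target built from the generated counts, unit costs and management
#' rates. Outputs pass [validate_country_params()] / [validate_population()]
#' unchanged and use the bundled-fixture schemas.
#'
#' @param spec A [synthetic_country_spec()].
#' @return A list with tibbles `params`, `population`, `targets`, plus the
#'   `seed` used.
#' @export
#' @examples
#' synth <- generate_countries(synthetic_country_spec(seed = 7))
#' calibrate_model(synth$params, synth$population, synth$targets)
generate_countries <- function(spec = synthetic_country_spec()) {
  stopifnot(inherits(spec, "synthetic_country_spec"))
  withr::with_seed(spec$seed, {
    k <- spec$n_countries
    code <- sprintf("S%02d", seq_len(k))
    d_hip <- runif_range(k, spec$dist_hip)
    d_ver <- runif_range(k, spec$dist_vertebral)
    params <- tibble::tibble(
      country = code,
      country_name = paste("Synthetic country", seq_len(k)),
      dist_hip = d_hip, dist_vertebral = d_ver, dist_nhnv = 1 - d_hip - d_ver,
      rr_hip = runif_range(k, spec$rr_hip),
      rr_vertebral = runif_range(k, spec$rr_vertebral),
      rr_nhnv = runif_range(k, spec$rr_nhnv),
      cost_hip = round(runif_range(k, spec$cost_hip)),
      cost_vertebral = round(runif_range(k, spec$cost_vertebral)),
      cost_nhnv = round(runif_range(k, spec$cost_nhnv)),
      med_cost_annual = round(runif_range(k, spec$med_cost_annual)),
      bmd_cost = round(runif_range(k, spec$bmd_cost)),
      treatment_rate = runif_range(k, spec$treatment_rate),
      identification_rate = runif_range(k, spec$identification_rate),
      at_risk_treatment_rate = runif_range(k, spec$at_risk_treatment_rate)
    )
    params <- validate_country_params(params)
    n0 <- round(exp(stats::runif(k, log(spec$population[1]),
                                 log(spec$population[2]))))
    g <- runif_range(k, spec$growth)
    population <- tidyr::expand_grid(i = seq_len(k), year = spec$years) |>
      dplyr::mutate(country = code[.data$i],
                    population = round(n0[.data$i] *
                                         (1 + g[.data$i])^(.data$year -
                                                             min(spec$years)))) |>
      dplyr::select("country", "year", "population")
    rate0 <- runif_range(k, spec$fracture_rate)
    targets <- population |>
      dplyr::mutate(
        rate = rate0[match(.data$country, code)] *
          stats::runif(dplyr::n(), 0.95, 1.05),
        fractures = round_half_up(.data$population * .data$rate / 1e5)) |>
      dplyr::select(-"rate")
    wuc <- params$dist_hip * params$cost_hip +
      params$dist_vertebral * params$cost_vertebral +
      params$dist_nhnv * params$cost_nhnv
    i <- match(targets$country, code)
    targets$cost_millions <-
      (targets$fractures * wuc[i] * stats::runif(nrow(targets), 0.95, 1.4) +
         targets$population * params$treatment_rate[i] *
         params$med_cost_annual[i] +
         targets$population * 0.25 * params$bmd_cost[i]) / 1e6
    targets$fractures_per_100k <- per_100k(targets$fractures,
                                           targets$population, digits = 0)
    targets$cost_per_100k <- per_100k(targets$cost_millions,
                                      targets$population, digits = 1)
    list(params = params, population = validate_population(population),
         targets = targets[, c("country", "year", "fractures",
                               "fractures_per_100k", "cost_millions",
                               "cost_per_100k")],
         seed = spec$seed)
  })
}

#' Microsimulate a cohort of women under the stratified model
#'
#' The microsimulation oracle for the cohort equations: `n` women are
#' assigned to strata and treatment/adherence states, then each records at
#' most one Bernoulli fracture per type per year. With the default
#' `"quantile"` assignment, cell occupancies are deterministic (rounded
#' expected sizes, treated women allocated to the at-risk stratum first,
#' mirroring the cohort model's targeting rule); with `"random"` assignment,
#' stratum membership and treatment are drawn at random (no risk targeting),
#' for sensitivity runs.
#'
#' @param n Number of women (>= 1).
#' @param profile A [risk_profile()].
#' @param rates One-row tibble of management rates.
#' @param rr Named per-type relative risks.
#' @param seed Integer seed; recorded in the output.
#' @param assignment `"quantile"` (default) or `"random"`.
#' @param nonadherent_efficacy See [population_risk()].
#' @return A tibble with one row per fracture type: simulated `count`, the
#'   cell-exact `expected` count, and the Monte-Carlo standard error `se`.
#' @export
#' @examples
#' pr <- risk_profile(c(hip = 0.01, vertebral = 0.008, nhnv = 0.03))
#' simulate_cohort(10000, pr, management_rates(0.25, 0.2, 0.4),
#'                 c(hip = 0.62, vertebral = 0.46, nhnv = 0.83), seed = 1)
simulate_cohort <- function(n, profile, rates, rr, seed = 1L,
                            assignment = c("quantile", "random"),
                            nonadherent_efficacy = 0) {
  stopifnot(inherits(profile, "risk_profile"), n >= 1)
  assignment <- match.arg(assignment)
  rr <- rr[fracture_types()]
  check_rr(rr, "rr")
  s <- profile$at_risk_share
  m <- profile$at_risk_multiplier
  tau <- rates$treatment_rate
  alpha <- rates$adherence_rate
  withr::with_seed(as.integer(seed), {
    if (assignment == "quantile") {
      n_ar <- round_half_up(n * s)
      n_tr <- round_half_up(n * tau)
      tr_ar <- min(n_tr, n_ar)
      tr_nar <- min(n_tr - tr_ar, n - n_ar)
    } else {
      n_ar <- stats::rbinom(1, n, s)
      n_tr <- stats::rbinom(1, n, tau)
      tr_ar <- if (n_tr > 0) stats::rhyper(1, n_ar, n - n_ar, n_tr) else 0
      tr_nar <- n_tr - tr_ar
    }
    adh_ar <- round_half_up(tr_ar * alpha)
    adh_nar <- round_half_up(tr_nar * alpha)
    if (assignment == "random") {
      adh_ar <- stats::rbinom(1, tr_ar, alpha)
      adh_nar <- stats::rbinom(1, tr_nar, alpha)
    }
    # cells: size, stratum multiplier, efficacy fraction applied
    cells <- data.frame(
      size = c(adh_ar, tr_ar - adh_ar, n_ar - tr_ar,
               adh_nar, tr_nar - adh_nar, (n - n_ar) - tr_nar),
      mult = c(m, m, m, 1, 1, 1),
      eff = c(1, nonadherent_efficacy, 0, 1, nonadherent_efficacy, 0)
    )
    out <- purrr::map(fracture_types(), function(ft) {
      p <- cap_probabilities(
        profile$base_rates[[ft]] * cells$mult *
          (1 - cells$eff * (1 - rr[[ft]])), warn = FALSE)
      draws <- stats::rbinom(nrow(cells), cells$size, p)
      tibble::tibble(type = ft, count = sum(draws),
                     expected = sum(cells$size * p),
                     se = sqrt(sum(cells$size * p * (1 - p))))
    })
    out <- dplyr::bind_rows(out)
    out$seed <- as.integer(seed)
    out
  })
}

#' Generate an individual-level synthetic cohort
#'
#' Draws ages (normal, truncated at 70), BMD T-scores (normal) and binary
#' clinical risk factors (independent Bernoulli at the given prevalences),
#' then evaluates the FRAX-like risk function for every woman. Used to
#' motivate the two-stratum summary the cohort model uses and for
#' sensitivity analyses of its constants.
#'
#' @param n Number of women.
#' @param seed Integer seed.
#' @param age_mean,age_sd Age distribution before truncation at 70.
#' @param tscore_mean,tscore_sd T-score distribution.
#' @param crf_prev Named prevalences for the risk factors of `params`.
#' @param params A [risk_function_params()].
#' @return A tibble with age, T-score, risk-factor flags and per-type annual
#'   fracture probabilities.
#' @export
generate_individuals <- function(n, seed = 1L, age_mean = 79, age_sd = 6.5,
                                 tscore_mean = -1.8, tscore_sd = 1.2,
                                 crf_prev = c(prior_fracture = 0.30,
                                              parent_hip = 0.12,
                                              smoking = 0.12,
                                              glucocorticoids = 0.05,
                                              rheumatoid = 0.04,
                                              alcohol = 0.05),
                                 params = risk_function_params()) {
  stopifnot(setequal(names(crf_prev), rownames(params$crf_multipliers)))
  crf_prev <- crf_prev[rownames(params$crf_multipliers)]
  withr::with_seed(as.integer(seed), {
    age <- 70 + abs(stats::rnorm(n, age_mean - 70, age_sd))
    t_score <- stats::rnorm(n, tscore_mean, tscore_sd)
    flags <- vapply(crf_prev, function(p) stats::rbinom(n, 1, p),
                    numeric(n))
    if (n == 1) flags <- matrix(flags, nrow = 1,
                                dimnames = list(NULL, names(crf_prev)))
    risks <- frax_like_risk(age, t_score, flags, params)
    dplyr::bind_cols(tibble::tibble(age = age, t_score = t_score),
                     tibble::as_tibble(flags), risks)
  })
}

#' Summarise an individual cohort into a two-stratum risk profile
#'
#' Ranks women by total annual fracture risk; the top `at_risk_share` form
#' the at-risk stratum. Returns the empirical baseline (not-at-risk mean)
#' rates and the realised at-risk multiplier, i.e. the stratified summary the
#' cohort model works with.
#'
#' @param individuals Output of [generate_individuals()].
#' @param at_risk_share Share defining the high-risk stratum.
#' @return A [risk_profile()].
#' @export
summarise_risk_profile <- function(individuals, at_risk_share = 0.30) {
  total <- individuals$hip + individuals$vertebral + individuals$nhnv
  cut <- stats::quantile(total, 1 - at_risk_share, names = FALSE)
  hi <- total >= cut
  base <- vapply(fracture_types(), function(ft) mean(individuals[[ft]][!hi]),
                 numeric(1))
  hi_mean <- vapply(fracture_types(), function(ft) mean(individuals[[ft]][hi]),
                    numeric(1))
  mult <- max(1, mean(hi_mean / base))
  risk_profile(base, at_risk_share, min(mult, 1 / max(base)))
}
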