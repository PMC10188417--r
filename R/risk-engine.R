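# Risk engine: per-type annual fracture probabilities for a country-year
# population under given management rates.
#
# The population is represented as a two-stratum mixture: a high-risk ("at
# risk") stratum holding a share `at_risk_share` of women whose per-type
# annual probability is `at_risk_multiplier` times the baseline stratum's.
# Treatment targets the at-risk stratum first (the care cascade runs
# assessment -> identification of those at risk -> treatment), spilling over
# to the baseline stratum only once the at-risk stratum is saturated.
# Treated-and-adherent women have their per-type probability multiplied by the
# treatment-mix relative risk; treated non-adherent women retain their
# untreated probability (an optional partial-efficacy fraction is exposed).

#' Construct a stratified risk profile
#'
#' @param base_rates Named numeric vector of per-type annual fracture
#'   probabilities for the baseline (not-at-risk) stratum; names must be
#'   `hip`, `vertebral`, `nhnv`.
#' @param at_risk_share Fraction of the population in the high-risk stratum
#'   (default 0.30; a model constant, not an estimate).
#' @param at_risk_multiplier Ratio (>= 1) of at-risk to baseline per-type
#'   probability (default 4.0; a model constant, not an estimate).
#' @return A list of class `risk_profile`.
#' @export
#' @examples
#' risk_profile(c(hip = 0.011, vertebral = 0.007, nhnv = 0.035))
risk_profile <- function(base_rates, at_risk_share = 0.30,
                         at_risk_multiplier = 4.0) {
  if (!setequal(names(base_rates), fracture_types())) {
    stop("`base_rates` must be named hip, vertebral, nhnv", call. = FALSE)
  }
  base_rates <- base_rates[fracture_types()]
  check_fraction(base_rates, "base_rates")
  check_fraction(at_risk_share, "at_risk_share")
  if (!is.finite(at_risk_multiplier) || at_risk_multiplier < 1) {
    stop("`at_risk_multiplier` must be >= 1", call. = FALSE)
  }
  if (any(base_rates * at_risk_multiplier > 1)) {
    stop("at-risk per-type probability exceeds 1; reduce base rates or ",
         "multiplier", call. = FALSE)
  }
  structure(list(base_rates = base_rates,
                 at_risk_share = at_risk_share,
                 at_risk_multiplier = at_risk_multiplier),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat("<risk_profile>\n")
  cat("  base rates:", paste(sprintf("%s %.5f", names(x$base_rates),
                                     x$base_rates), collapse = ", "), "\n")
  cat(sprintf("  at-risk share %.2f, multiplier %.2f\n",
              x$at_risk_share, x$at_risk_multiplier))
  invisible(x)
}

# Mixture factor such that population-average risk = base_rate * factor.
# Linear in the base rate, so calibration inverts it in closed form.
# kappa is the realised per-woman risk reduction among the treated:
# (1 - RR) * (adherent share + non-adherent share * partial efficacy).
risk_mixture_factor <- function(rr, rates, at_risk_share, at_risk_multiplier,
                                nonadherent_efficacy = 0) {
  s <- at_risk_share
  m <- at_risk_multiplier
  tau <- rates$treatment_rate
  kappa <- (1 - rr) * (rates$adherence_rate +
                         (1 - rates$adherence_rate) * nonadherent_efficacy)
  t_ar <- if (s > 0) pmin(tau, s) / s else 0       # treated share within at-risk
  t_nar <- if (s < 1) pmax(tau - s, 0) / (1 - s) else 0  # spillover share
  s * m * (1 - t_ar * kappa) + (1 - s) * (1 - t_nar * kappa)
}

#' Population-average annual fracture risk under management rates
#'
#' Mixes the stratified profile over the four (stratum x treatment-state)
#' cells: at-risk/baseline crossed with treated-adherent, treated
#' non-adherent and untreated. Treated women are drawn from the at-risk
#' stratum first; any excess spills over to the baseline stratum (never an
#' error).
#'
#' @param profile A [risk_profile()].
#' @param rates A one-row tibble of management rates, e.g. from
#'   [management_rates()] or a row of [apply_intervention()] output.
#' @param rr Named per-type treatment relative risks (`hip`, `vertebral`,
#'   `nhnv`), each in `(0, 1]`.
#' @param nonadherent_efficacy Fraction of full treatment efficacy retained
#'   by treated non-adherent women (default 0: no benefit without adherence).
#' @return Named per-type population-average annual probabilities.
#' @export
#' @examples
#' pr <- risk_profile(c(hip = 0.01, vertebral = 0.01, nhnv = 0.01),
#'                    at_risk_share = 0.3, at_risk_multiplier = 4)
#' population_risk(pr, management_rates(0.25, 0.2, 0.4),
#'                 c(hip = 0.62, vertebral = 0.46, nhnv = 0.83))
population_risk <- function(profile, rates, rr, nonadherent_efficacy = 0) {
  stopifnot(inherits(profile, "risk_profile"))
  if (!setequal(names(rr), fracture_types())) {
    stop("`rr` must be named hip, vertebral, nhnv", call. = FALSE)
  }
  rr <- rr[fracture_types()]
  check_rr(rr, "rr")
  check_fraction(nonadherent_efficacy, "nonadherent_efficacy")
  fac <- risk_mixture_factor(rr, rates, profile$at_risk_share,
                             profile$at_risk_multiplier, nonadherent_efficacy)
  cap_probabilities(profile$base_rates * fac, warn = FALSE)
}

#' Clip per-type probabilities to the unit interval
#'
#' The model permits at most one fracture per type per woman-year, so every
#' per-type annual probability is capped at 1 (and floored at 0), with a
#' warning when clipping occurs.
#'
#' @param risk Numeric vector of per-type probabilities.
#' @param warn Emit a warning when a value is clipped (default `TRUE`).
#' @return The clipped vector.
#' @export
#' @examples
#' cap_probabilities(c(hip = 0.5, vertebral = 0.2, nhnv = 1.3))
cap_probabilities <- function(risk, warn = TRUE) {
  out <- pmin(pmax(risk, 0), 1)
  if (warn && any(out != risk, na.rm = TRUE)) {
    warning("per-type probability clipped to [0, 1]", call. = FALSE)
  }
  out
}

# FRAX-like generative risk function ------------------------------------------

#' Parameters of the FRAX-like risk function
#'
#' A generative stand-in for a fracture-risk assessment tool: per fracture
#' type, an annual baseline probability at the reference point (age 70,
#' T-score 0, no clinical risk factors), a log-linear (Gompertz-style) age
#' slope on the hazard, a gradient of risk per T-score standard deviation,
#' and multiplicative clinical-risk-factor (CRF) effects. Default values are
#' package constants chosen to give realistic orders of magnitude for women
#' aged 70+ (hip incidence roughly doubling every 6-7 years of age; hip risk
#' most sensitive to BMD); they are not estimates from any published
#' coefficient table.
#'
#' @param base_rate,age_slope,gradient_per_sd Named per-type vectors: annual
#'   baseline probability in `(0, 1)`, hazard log-slope per year of age, and
#'   hazard ratio per T-score SD below 0.
#' @param crf_multipliers Matrix of hazard multipliers, one row per clinical
#'   risk factor, columns `hip`, `vertebral`, `nhnv`.
#' @return A list of class `risk_function_params`.
#' @export
risk_function_params <- function(
    base_rate = c(hip = 0.004, vertebral = 0.004, nhnv = 0.013),
    age_slope = c(hip = 0.11, vertebral = 0.06, nhnv = 0.03),
    gradient_per_sd = c(hip = 2.6, vertebral = 1.8, nhnv = 1.5),
    crf_multipliers = rbind(
      prior_fracture  = c(hip = 1.8, vertebral = 2.0, nhnv = 1.7),
      parent_hip      = c(hip = 1.6, vertebral = 1.2, nhnv = 1.2),
      smoking         = c(hip = 1.4, vertebral = 1.2, nhnv = 1.2),
      glucocorticoids = c(hip = 1.6, vertebral = 1.7, nhnv = 1.3),
      rheumatoid      = c(hip = 1.4, vertebral = 1.3, nhnv = 1.2),
      alcohol         = c(hip = 1.5, vertebral = 1.4, nhnv = 1.3))) {
  ft <- fracture_types()
  stopifnot(setequal(names(base_rate), ft), setequal(names(age_slope), ft),
            setequal(names(gradient_per_sd), ft),
            setequal(colnames(crf_multipliers), ft))
  if (any(base_rate <= 0 | base_rate >= 1)) {
    stop("`base_rate` must lie in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(age_slope))) stop("`age_slope` must be finite",
                                       call. = FALSE)
  if (any(gradient_per_sd <= 0) || any(crf_multipliers <= 0)) {
    stop("risk multipliers must be positive", call. = FALSE)
  }
  structure(list(base_rate = base_rate[ft], age_slope = age_slope[ft],
                 gradient_per_sd = gradient_per_sd[ft],
                 crf_multipliers = crf_multipliers[, ft, drop = FALSE]),
            class = "risk_function_params")
}

#' FRAX-like per-type annual fracture probability for an individual
#'
#' Hazard-scale composition: the reference annual probability is converted to
#' a hazard, multiplied by `exp(age_slope * (age - 70))`, by
#' `gradient_per_sd^(-t_score)` (risk rises as the T-score falls below 0) and
#' by the product of the multipliers of the risk factors present, then
#' converted back to an annual probability (`1 - exp(-h)`), which caps it
#' below 1. At the reference point the per-type baselines are returned
#' exactly.
#'
#' @param age Age(s) in years, must be >= 70.
#' @param t_score BMD T-score(s) in SD (negative = lower bone density).
#' @param crf_flags 0/1 indicator vector (or matrix, individuals x factors)
#'   over the risk factors of `params$crf_multipliers`.
#' @param params A [risk_function_params()].
#' @return A tibble with columns `hip`, `vertebral`, `nhnv` (one row per
#'   individual).
#' @export
#' @examples
#' frax_like_risk(70, 0, rep(0, 6))
#' frax_like_risk(80, -2.5, c(1, 0, 0, 0, 0, 0))
frax_like_risk <- function(age, t_score, crf_flags,
                           params = risk_function_params()) {
  if (any(age < 70)) {
    stop("`age` must be >= 70: the model population is women aged 70+",
         call. = FALSE)
  }
  n_fac <- nrow(params$crf_multipliers)
  flags <- if (is.matrix(crf_flags)) crf_flags else
    matrix(crf_flags, ncol = n_fac, byrow = TRUE)
  stopifnot(ncol(flags) == n_fac, all(flags %in% c(0, 1)))
  n <- max(length(age), length(t_score), nrow(flags))
  age <- rep_len(age, n)
  t_score <- rep_len(t_score, n)
  if (nrow(flags) == 1 && n > 1) {
    flags <- flags[rep(1, n), , drop = FALSE]
  }
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, fracture_types()))
  for (ft in fracture_types()) {
    h0 <- -log(1 - params$base_rate[[ft]])
    crf_term <- exp(flags %*% log(params$crf_multipliers[, ft]))
    h <- h0 * exp(params$age_slope[[ft]] * (age - 70)) *
      params$gradient_per_sd[[ft]]^(-t_score) * as.numeric(crf_term)
    out[, ft] <- 1 - exp(-h)
  }
  tibble::as_tibble(out)
}
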