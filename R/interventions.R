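# Intervention engine: transforms status-quo management rates (assessment,
# treatment, adherence) into the rates in force under a hypothetical
# disease-management intervention at a given improvement fraction.

#' Improved adherence rate
#'
#' An adherence intervention removes a fraction `f` of the *non-adherence*:
#' `new = a + f * (1 - a)`. A 50% reduction of non-adherence from a 40%
#' baseline therefore yields 70% adherence.
#'
#' @param adherence_sq Status-quo adherence fraction in `[0, 1]`.
#' @param f Improvement fraction in `[0, 1]`.
#' @return New adherence fraction, in `[adherence_sq, 1]`.
#' @export
#' @examples
#' improved_adherence_rate(0.40, 0.50) # 0.70
improved_adherence_rate <- function(adherence_sq, f) {
  check_fraction(adherence_sq, "adherence_sq")
  check_fraction(f, "f")
  adherence_sq + f * (1 - adherence_sq)
}

#' Improved risk-assessment rate
#'
#' Two documented interpretations of an "X% improvement in risk assessment
#' rates" are supported:
#' * `"relative"` (default): `min(a * (1 + f), 1)` — a 50% improvement takes
#'   25% assessment to 37.5%;
#' * `"gap"`: `a + f * (1 - a)` — the same gap-closure arithmetic as the
#'   adherence lever, taking 25% to 62.5% at `f = 0.5`.
#'
#' @param assessment_sq Status-quo assessment fraction in `[0, 1]`.
#' @param f Improvement fraction in `[0, 1]`.
#' @param mode `"relative"` or `"gap"`.
#' @return New assessment fraction in `[assessment_sq, 1]`.
#' @export
#' @examples
#' improved_assessment_rate(0.25, 0.5) # 0.375
#' improved_assessment_rate(0.25, 0.5, mode = "gap") # 0.625
improved_assessment_rate <- function(assessment_sq, f,
                                     mode = c("relative", "gap")) {
  mode <- match.arg(mode)
  check_fraction(assessment_sq, "assessment_sq")
  check_fraction(f, "f")
  if (mode == "relative") {
    pmin(assessment_sq * (1 + f), 1)
  } else {
    assessment_sq + f * (1 - assessment_sq)
  }
}

#' Treatment uptake from an improved assessment rate
#'
#' Additional assessment translates into additional treatment through the
#' care cascade: of the newly assessed, a country-specific fraction is
#' identified as at risk, and of those a country-specific fraction is
#' treated:
#' `new = treatment_sq + (assessment_new - assessment_sq) *
#'   identification_rate * at_risk_treatment_rate`,
#' clipped at 1 (with a warning) should the sum exceed unity.
#'
#' @param treatment_sq Status-quo population treatment rate.
#' @param assessment_new,assessment_sq New and status-quo assessment rates;
#'   `assessment_new` must not be below `assessment_sq` (interventions never
#'   reduce assessment).
#' @param identification_rate Fraction of assessed women identified at risk.
#' @param at_risk_treatment_rate Fraction of identified women treated.
#' @return New population treatment rate in `[treatment_sq, 1]`.
#' @export
#' @examples
#' new_treatment_rate(0.22, 0.375, 0.25, 0.57, 0.33)
new_treatment_rate <- function(treatment_sq, assessment_new, assessment_sq,
                               identification_rate, at_risk_treatment_rate) {
  check_fraction(treatment_sq, "treatment_sq")
  check_fraction(assessment_new, "assessment_new")
  check_fraction(assessment_sq, "assessment_sq")
  check_fraction(identification_rate, "identification_rate")
  check_fraction(at_risk_treatment_rate, "at_risk_treatment_rate")
  if (any(assessment_new < assessment_sq)) {
    stop("`assessment_new` must be >= `assessment_sq`: ",
         "interventions never reduce assessment", call. = FALSE)
  }
  out <- treatment_sq + (assessment_new - assessment_sq) *
    identification_rate * at_risk_treatment_rate
  if (any(out > 1)) {
    warning("treatment rate clipped at 1", call. = FALSE)
    out <- pmin(out, 1)
  }
  out
}

#' Specify a disease-management intervention
#'
#' @param lever Which management lever(s) to improve: `"assessment"` (risk
#'   assessment, which raises treatment uptake through the care cascade),
#'   `"adherence"` (reduction of non-adherence among the treated),
#'   `"combined"` (both, hierarchically: the treated population is first
#'   enlarged via the new assessment rate, then the new adherence rate is
#'   applied to it), or `"status_quo"` (no change; equivalent to any lever at
#'   `improvement = 0`).
#' @param improvement Improvement fraction `f` in `[0, 1]`; the published
#'   scenarios use 0.10, 0.50 and 1.00.
#' @param assessment_mode Interpretation of the assessment improvement, see
#'   [improved_assessment_rate()].
#' @param label Scenario label; defaults to e.g. `"1_50"`, `"2_10"`, `"3_100"`
#'   (lever number underscore percent) or `"status_quo"`.
#' @return A one-row tibble of class `intervention_spec`.
#' @export
#' @examples
#' intervention_spec("combined", 0.5)
intervention_spec <- function(lever = c("assessment", "adherence", "combined",
                                        "status_quo"),
                              improvement = 0.5,
                              assessment_mode = c("relative", "gap"),
                              label = NULL) {
  lever <- match.arg(lever)
  assessment_mode <- match.arg(assessment_mode)
  check_fraction(improvement, "improvement")
  if (lever == "status_quo") improvement <- 0
  if (is.null(label)) {
    label <- if (lever == "status_quo" || improvement == 0) {
      "status_quo"
    } else {
      lever_no <- match(lever, c("assessment", "adherence", "combined"))
      sprintf("%d_%g", lever_no, 100 * improvement)
    }
  }
  out <- tibble::tibble(label = label, lever = lever,
                        improvement = improvement,
                        assessment_mode = assessment_mode)
  class(out) <- c("intervention_spec", class(out))
  out
}

#' The published scenario grid
#'
#' Status quo plus the three levers at 50% (main analysis) and at 10% and
#' 100% (scenario analyses).
#'
#' @param assessment_mode Interpretation of assessment improvements, see
#'   [improved_assessment_rate()].
#' @return A tibble of scenario specifications, one row each.
#' @export
default_scenarios <- function(assessment_mode = "relative") {
  specs <- list(intervention_spec("status_quo"))
  for (f in c(0.5, 0.1, 1.0)) {
    for (lever in c("assessment", "adherence", "combined")) {
      specs <- c(specs, list(
        intervention_spec(lever, f, assessment_mode = assessment_mode)))
    }
  }
  dplyr::bind_rows(specs)
}

#' Management rates in force under an intervention
#'
#' Applies an intervention specification to each country's status-quo
#' management pattern. The assessment lever changes the assessment rate and,
#' through the uptake cascade, the treatment rate; the adherence lever changes
#' only adherence; the combined lever applies both (treatment uptake is
#' computed from the new assessment rate first, then the improved adherence
#' applies to the enlarged treated population). At `improvement = 0` the
#' status-quo rates are returned bit-exactly.
#'
#' @param params Country-parameter tibble from [read_country_params()].
#' @param spec An [intervention_spec()] (one row).
#' @param assumptions Global assumptions from [global_assumptions()].
#' @return A tibble with one row per country: `country`, `assessment_rate`,
#'   `treatment_rate`, `adherence_rate`.
#' @export
#' @examples
#' params <- read_country_params()
#' apply_intervention(params, intervention_spec("combined", 0.5))
apply_intervention <- function(params, spec,
                               assumptions = global_assumptions()) {
  stopifnot(nrow(spec) == 1)
  f <- spec$improvement
  a_sq <- assumptions$assessment_rate
  adh_sq <- assumptions$adherence_rate
  assessment <- rep(a_sq, nrow(params))
  treatment <- params$treatment_rate
  adherence <- rep(adh_sq, nrow(params))
  if (f > 0 && spec$lever %in% c("assessment", "combined")) {
    assessment <- rep(
      improved_assessment_rate(a_sq, f, spec$assessment_mode), nrow(params))
    treatment <- new_treatment_rate(
      params$treatment_rate, assessment, a_sq,
      params$identification_rate, params$at_risk_treatment_rate)
  }
  if (f > 0 && spec$lever %in% c("adherence", "combined")) {
    adherence <- rep(improved_adherence_rate(adh_sq, f), nrow(params))
  }
  tibble::tibble(country = params$country,
                 assessment_rate = assessment,
                 treatment_rate = treatment,
                 adherence_rate = adherence)
}

#' Construct a set of management rates directly
#'
#' @param assessment_rate,treatment_rate,adherence_rate Fractions in `[0, 1]`.
#' @return A one-row tibble.
#' @export
management_rates <- function(assessment_rate, treatment_rate, adherence_rate) {
  check_fraction(assessment_rate, "assessment_rate")
  check_fraction(treatment_rate, "treatment_rate")
  check_fraction(adherence_rate, "adherence_rate")
  tibble::tibble(assessment_rate = assessment_rate,
                 treatment_rate = treatment_rate,
                 adherence_rate = adherence_rate)
}
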