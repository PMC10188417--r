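# Independent oracles and small in-code fixtures used across tests.
# These deliberately re-derive quantities from first principles (explicit
# cell enumeration, bisection) rather than calling the package's own
# mixture arithmetic.

# Population-average per-type risk by exhaustive enumeration over the six
# (stratum x treatment-state) cells.
enum_pop_risk <- function(base, share, mult, treatment, adherence, rr) {
  tr_ar <- min(treatment, share)
  tr_nar <- max(treatment - share, 0)
  w <- c(tr_ar * adherence, tr_ar * (1 - adherence), share - tr_ar,
         tr_nar * adherence, tr_nar * (1 - adherence),
         (1 - share) - tr_nar)
  p <- base * c(mult * rr, mult, mult, rr, 1, 1)
  sum(w * pmin(p, 1))
}

# Solve the baseline rate hitting a target population-average risk by
# bisection on the enumeration oracle.
bisect_base <- function(target, share, mult, treatment, adherence, rr,
                        tol = 1e-14) {
  lo <- 0
  hi <- 1 / mult
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (enum_pop_risk(mid, share, mult, treatment, adherence, rr) < target) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# A small two-country parameter table satisfying all input invariants.
toy_params <- function() {
  validate_country_params(tibble::tibble(
    country = c("AA", "BB"),
    country_name = c("Alpha", "Beta"),
    dist_hip = c(0.20, 0.18), dist_vertebral = c(0.15, 0.12),
    dist_nhnv = c(0.65, 0.70),
    rr_hip = c(0.60, 0.62), rr_vertebral = c(0.45, 0.50),
    rr_nhnv = c(0.80, 0.83),
    cost_hip = c(12000, 8000), cost_vertebral = c(3000, 2000),
    cost_nhnv = c(5000, 4000),
    med_cost_annual = c(200, 100), bmd_cost = c(40, 25),
    treatment_rate = c(0.20, 0.10),
    identification_rate = c(0.55, 0.60),
    at_risk_treatment_rate = c(0.30, 0.20)
  ))
}

toy_population <- function() {
  tidyr::expand_grid(country = c("AA", "BB"), year = snapshot_years()) |>
    dplyr::mutate(population = ifelse(country == "AA", 1000000, 500000) +
                    1000 * (year - 2020))
}

toy_targets <- function() {
  toy_population() |>
    dplyr::mutate(fractures = round(population * 0.05),
                  cost_millions = fractures * 6000 / 1e6 +
                    population * 0.02 * 200 / 1e6 + population * 0.25 * 40 / 1e6)
}

belgium_row <- function() {
  p <- read_country_params()
  p[p$country == "BE", ]
}
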