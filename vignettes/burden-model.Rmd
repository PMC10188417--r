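---
title: "A cross-sectional cohort model of osteoporotic fracture burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cross-sectional cohort model of osteoporotic fracture burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoburden)
library(dplyr)
```

## The model

`osteoburden` estimates the annual clinical and economic burden of
osteoporotic fractures among women aged 70 years and older, and the net
benefit of hypothetical improvements in disease management. It is a
population-level, *cross-sectional* cohort model: each snapshot year
(2020, 2025, 2030, 2035, 2040) is evaluated independently from that year's
population size and management pattern. There is no longitudinal state —
no incident/prevalent dynamics, no mortality, no persistence curves.

For a country with $N$ women aged 70+, the model proceeds in four steps.

**1. Fracture risk.** Each woman faces annual probabilities
$p_t$ of fracture for three types $t$: hip, vertebral, and non-hip
non-vertebral (NHNV), with at most one fracture per type per year. The
population is summarised as a two-stratum mixture: a high-risk stratum
holding a share $s$ of women whose per-type probability is $m \ge 1$ times
the baseline stratum's rate $b_t$. The population-average untreated risk is
$b_t\,(sm + 1 - s)$.

**2. Treatment effect.** A fraction $\tau$ of women is treated, drawn from
the at-risk stratum first (the care pathway is assessment → identification
of those at risk → treatment, so the treated carry elevated risk); any
excess spills into the baseline stratum. Among the treated, a fraction
$\alpha$ adheres and receives the treatment-mix relative risk $RR_t$; the
non-adherent receive no benefit (a partial-efficacy fraction is exposed and
defaults to 0). The per-type population risk is linear in $b_t$:

$$p_t = b_t\left[(sm + 1 - s) - \kappa_t \sum_{\text{strata}} m_j \tau_j\right],
\qquad \kappa_t = (1 - RR_t)\,\alpha,$$

where $\tau_j$ is the treated share drawn from stratum $j$ (multiplier
$m_j$). `population_risk()` evaluates this; the microsimulation in
`simulate_cohort()` is its individual-level oracle.

**3. Counts.** Expected fractures are $N p_t$ per type. All arithmetic is
real-valued; counts are rounded (half away from zero) only at reporting
boundaries, because a cohort expectation — not a stochastic draw — is the
estimand.

**4. Costs.** Three components, in 2020 euros: fracture care (per-type
counts × first-year direct unit costs), medication ($N\tau$ × annual
medication cost, charged for all treated women regardless of adherence;
an adherence-scaled option exists), and risk assessment ($N a$ × unit cost
of a BMD measurement at assessment rate $a$, incurred annually). Totals are
reported in € millions and per 100,000 women.

## Management levers

Status quo: assessment $a = 25\%$ and adherence $\alpha = 40\%$ in every
country; the population treatment rate $\tau$ is country-specific. Three
interventions, each at an improvement fraction $f \in \{0.10, 0.50, 1.00\}$:

* **Assessment** (`1_f`): the assessment rate improves and feeds treatment
  uptake through the care cascade,
  $\tau' = \tau + (a' - a) \cdot \text{identification rate} \cdot
  \text{at-risk treatment rate}$, clipped at 1.
* **Adherence** (`2_f`): non-adherence shrinks by $f$,
  $\alpha' = \alpha + f(1 - \alpha)$ — e.g. 40% → 70% at $f = 0.5$.
* **Combined** (`3_f`): hierarchical composition — uptake is computed from
  the improved assessment rate first, then the improved adherence applies
  to the enlarged treated population.

Two readings of an "$f$ improvement in assessment" are supported and are
first-class options: `relative` ($a' = \min(a(1+f), 1)$, the default:
a 100% improvement from 25% lands at 50%) and `gap`
($a' = a + f(1-a)$, the same arithmetic as the adherence lever). Neither is
hard-coded as canonical; `default_scenarios(assessment_mode = )` switches
the whole grid.

## Calibration

Observed burden (bundled transcriptions of published country-level tables,
or any user table in the same schema) pins the model to reality.
`calibrate_model()`:

* splits the observed all-type fracture rate across types in proportion to
  the country's fracture-type distribution, and inverts the (linear)
  mixture factor in closed form to get $b_t$ — so a status-quo run
  reproduces the observed counts to floating-point accuracy;
* solves a multiplicative scale on the *fracture-cost component only* so
  the modelled cost total matches the observed total. Medication and
  assessment components stay structural, since their unit costs and rates
  are printed inputs; the unprinted residual lies in fracture-care
  pathways. Factors land between 0.92 and 1.02 for seven of the eight
  bundled countries. France is the exception (≈1.8): its observed cost
  total implies roughly €14.7k per fracture while its printed unit costs
  imply ≈€8.1k — an inconsistency in the source tables that the scale
  factor absorbs and `calibration_report()` logs.

A useful identity: under the status quo the calibrated output is invariant
to the at-risk multiplier $m$ (it only redistributes risk between strata),
which the test suite asserts by sweeping $m$. Interventions, by contrast,
*do* depend on $m$, because newly treated women enter at the at-risk rate
$m b_t$.

### Stratification constants

`at_risk_share = 0.30` and `at_risk_multiplier = 4.0` are model constants,
not estimates: they are reported in all outputs and configurable
everywhere. With these defaults the at-risk stratum of a typical country
carries roughly a 12% all-type annual fracture probability versus ~3% in
the baseline stratum, consistent with what FRAX-style tools label "high
risk" at these ages. They are deliberately not jointly estimated from the
burden tables — share and multiplier are unidentifiable from a single
population-average rate.

## What the model will and will not reproduce

Calibration makes the status-quo tables reproducible essentially exactly
(the bundled tables' own totals differ from the sum of their printed rows
by ±1–2 units, because they were computed before rounding; tests compare
at printed precision). Intervention *deltas* are a different matter: the
published deltas of this model family depend on the full individual-level
risk distribution, which a calibrated two-stratum mixture cannot carry.
The package therefore treats intervention output as qualitative: identity
at $f = 0$, monotonicity in $f$, and combined-lever dominance on fractures
all hold structurally and are tested.

One substantive finding of this reconstruction deserves emphasis: under
the cost decomposition above, the assessment lever *increases* total costs.
Its added medication and BMD spending exceeds the fracture savings that any
calibrated mixture can deliver — the savings are bounded by
$b_t m \le (\text{observed rate})/s$ even as $m \to \infty$, and that bound
sits several-fold below the added spending at the bundled unit costs (e.g.
Belgium at $f=0.5$: ≈€8.5M added vs ≤€2.9M saved). Consequently cost-side
dominance of the combined lever over the adherence-only lever also fails:
the combined lever carries intervention costs the adherence lever does not.
Published analyses reporting net savings from assessment implicitly assume
a far stronger concentration of risk among the newly identified than any
two-point mixture calibrated to a population-average rate can represent.
The corresponding acceptance-level assertions are kept in the suite and
fail visibly rather than being weakened; fracture-side assertions pass.

## Synthetic data and the microsimulation oracle

`generate_countries()` draws full input sets — parameter tables, population
projections, calibration targets — uniformly within ranges defaulting to
the spread observed across the eight bundled countries (fracture mixes
around 1/5 hip, RRs strongest for vertebral fracture, unit costs spanning
the Central-European–Swiss range, base populations 0.25–8M log-uniform with
1–3% annual growth, all-type rates 2,800–8,000 per 100,000). A single
seeded stream fully determines the output, and outputs pass every input
validation, so synthetic and bundled fixtures are interchangeable.

`simulate_cohort()` is the central cross-check: women are assigned to the
six (stratum × treatment-state) cells — deterministically by rounded
expected size with treated women placed in the at-risk stratum first,
mirroring the cohort model's targeting (a fully random assignment mode
exists for sensitivity runs) — then each records at most one Bernoulli
fracture per type. The suite checks the law-of-large-numbers agreement at
$n = 10^5$ across 200 seeded parameter draws, requiring at least 99% of
per-type $z$-scores within 3 Monte-Carlo standard errors (0.27% exceedance
is expected for an exact match) and none beyond 4.5.

`frax_like_risk()` is a generative stand-in for a fracture-risk assessment
tool: per-type hazards composed of a Gompertz-style age term (hip hazard
roughly doubling every 6–7 years), a gradient of risk per T-score SD
(strongest for hip, 2.6 per SD), and multiplicative clinical-risk-factor
effects, converted to annual probabilities via $1 - e^{-h}$. Its
coefficients are package constants with realistic orders of magnitude, not
a reproduction of any published coefficient table; it feeds
`generate_individuals()` and motivates the two-stratum summary
(`summarise_risk_profile()`), but the calibrated pipeline never depends on
it.

What the synthetic generator does *not* emulate: correlated risk factors,
country-level correlation between costs and incidence, non-uniform
parameter distributions, and time-varying management patterns. Passing
tests on synthetic data therefore demonstrate the *arithmetic* of the
model, not the realism of any particular country's inputs.

## Numerical choices

* Rounding is half-away-from-zero (`round_half_up()`) at reporting
  boundaries only; fracture per-100k rates display to the integer, cost
  rates to €0.1 per 100k.
* Printed fracture-type percentages are rounded integers; shares are
  renormalised proportionally to sum to 1 (`dist_renorm` records the raw
  sum, 0.99–1.01 in the bundled table).
* Per-type probabilities are capped to $[0, 1]$ (at most one fracture per
  type per woman-year); treatment uptake is clipped at 1 with a warning.
* Calibration is closed-form; infeasible targets (an implied at-risk
  probability above 1, or an observed cost below the structural
  medication + assessment floor) raise diagnostic errors rather than
  silently clipping.
* Degenerate strata ($s = 0$ or $s = 1$) reduce to a single-stratum model;
  treated spillover beyond the at-risk stratum is handled by construction,
  never an error.

## Problem sizes

The test suite calibrates the full 8 × 5 bundled grid (closed-form, well
under a second), runs the ten-scenario grid, and exercises the
microsimulation at $n = 10^5$ for 200 parameter draws plus smaller
law-of-large-numbers checks at $n \in \{10^3, 2\times10^4\}$ — sizes chosen
so the entire suite completes in well under a minute while keeping the
Monte-Carlo standard errors small enough for 3-SE comparisons to be
informative.

## Worked example

```{r}
model <- calibrate_model(read_country_params(), read_population(),
                         read_burden_targets())
glance(model)

result <- run_scenarios(model, default_scenarios())
glance(result) |>
  select(scenario, fractures_2040, delta_fractures, pct_fractures)
```

```{r, fig.width = 7, fig.height = 3.5}
autoplot(result)
```

## Limitations

Beyond the reproduction limits above: men are excluded; only first-year
direct fracture costs are counted (no long-term nursing-home costs, no
indirect or societal costs, no discounting, no QALYs); adverse events and
drug switching are not modelled; each woman records at most one fracture
per type per year, so multiple same-type fractures are undercounted; and
healthcare unit costs are held constant across the horizon.
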