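test_that("expected fracture counts scale with population and risk", {
  out <- annual_fractures(100000, c(hip = 0.01, vertebral = 0.005,
                                    nhnv = 0.03))
  expect_equal(out$hip, 1000)
  expect_equal(out$total, out$hip + out$vertebral + out$nhnv)
  zero <- annual_fractures(5000, c(hip = 0, vertebral = 0, nhnv = 0))
  expect_equal(zero$total, 0)
  # rounding is half away from zero
  expect_equal(annual_fractures(1000, c(hip = 0.0105, vertebral = 0,
                                        nhnv = 0))$hip, 11)
})

test_that("cost components follow counts, unit costs and rates", {
  be <- belgium_row()
  counts <- c(hip = 10227, vertebral = 6818, nhnv = 31655)
  rates <- management_rates(0, 0, 0.4)
  out <- annual_costs(counts, be, rates, n = 909965)
  # independent sum: 10227*13381 + 6818*2959 + 31655*4932 = 313,144,409
  expect_equal(out$cost_fracture, 313.144409)
  expect_equal(out$cost_medication, 0)
  expect_equal(out$cost_assessment, 0)
  expect_equal(out$cost_total, out$cost_fracture)
  # doubling every count doubles the fracture component exactly
  out2 <- annual_costs(2 * counts, be, rates, n = 909965)
  expect_equal(out2$cost_fracture, 2 * out$cost_fracture)
  # structural components
  sq <- management_rates(0.25, 0.22, 0.4)
  full <- annual_costs(counts, be, sq, n = 909965)
  expect_equal(full$cost_medication, 909965 * 0.22 * 216 / 1e6)
  expect_equal(full$cost_assessment, 909965 * 0.25 * 34 / 1e6)
  expect_equal(full$cost_total,
               full$cost_fracture + full$cost_medication +
                 full$cost_assessment)
  # zero everything -> zero
  none <- annual_costs(c(hip = 0, vertebral = 0, nhnv = 0), be,
                       management_rates(0, 0, 0), n = 1)
  expect_equal(none$cost_total, 0)
})

test_that("per-100,000 normalisation reproduces published example cells", {
  expect_equal(per_100k(48700, 909965, digits = 0), 5352)
  expect_equal(per_100k(50952, 665515, digits = 0), 7656)
  expect_equal(per_100k(0, 123456), 0)
  expect_equal(per_100k(343, 909965, digits = 1), 37.7)
  expect_error(per_100k(10, 0), "positive")
})

test_that("net benefit differences intervention outcomes from the status quo", {
  sq <- tibble::tibble(year = 2020, fractures = 1238320, cost_total = 12790)
  same <- net_benefit(sq, dplyr::mutate(sq, scenario = "x"))
  expect_equal(same$delta_fractures, 0)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$pct_fractures, 0)
  iv <- tibble::tibble(scenario = "3_50", year = 2020, fractures = 1020477,
                       cost_total = 12790 / 2)
  nb <- net_benefit(sq, iv)
  expect_equal(nb$delta_fractures, -217843)
  expect_equal(round_half_up(nb$pct_fractures, 1), -17.6)
  expect_equal(nb$pct_cost, -50)
  expect_error(net_benefit(sq, dplyr::mutate(iv, year = 2025)), "mismatch")
})

test_that("aggregation conserves counts and costs and recomputes rates", {
  mod <- calibrate_model(toy_params(), toy_population(), toy_targets())
  burden <- estimate_burden(mod)
  agg <- aggregate_burden(burden)
  by_year <- split(burden, burden$year)
  for (y in names(by_year)) {
    a <- agg[agg$year == as.numeric(y), ]
    expect_equal(a$population, sum(by_year[[y]]$population))
    expect_equal(a$fractures, sum(by_year[[y]]$fractures))
    expect_equal(a$cost_total, sum(by_year[[y]]$cost_total))
    expect_equal(a$fractures_per_100k,
                 a$fractures / a$population * 1e5)
  }
  expect_error(aggregate_burden(burden[burden$country == "AA", ],
                                countries = c("AA", "BB")), "BB")
  solo <- aggregate_burden(burden[burden$country == "AA", ],
                           countries = "AA")
  expect_equal(solo$fractures,
               burden$fractures[burden$country == "AA"])
})

test_that("burden is scale-equivariant in population size", {
  k <- 3
  pop <- toy_population()
  mod1 <- calibrate_model(toy_params(), pop, toy_targets())
  pop_k <- dplyr::mutate(pop, population = population * k)
  tg_k <- dplyr::mutate(toy_targets(), fractures = fractures * k,
                        cost_millions = cost_millions * k)
  mod_k <- calibrate_model(toy_params(), pop_k, tg_k)
  b1 <- estimate_burden(mod1, intervention_spec("combined", 0.5))
  bk <- estimate_burden(mod_k, intervention_spec("combined", 0.5))
  expect_equal(bk$fx_hip, k * b1$fx_hip, tolerance = 1e-9)
  expect_equal(bk$cost_total, k * b1$cost_total, tolerance = 1e-9)
  expect_equal(bk$fractures_per_100k, b1$fractures_per_100k,
               tolerance = 1e-9)
})
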