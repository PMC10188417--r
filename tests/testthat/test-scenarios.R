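model_fixture <- NULL
get_model <- function() {
  if (is.null(model_fixture)) {
    model_fixture <<- calibrate_model(read_country_params(),
                                      read_population(),
                                      read_burden_targets())
  }
  model_fixture
}

test_that("the status-quo scenario reproduces the calibrated fixture burden", {
  sq <- estimate_burden(get_model())
  tg <- read_burden_targets()
  cmp <- dplyr::inner_join(sq, tg, by = c("country", "year"))
  expect_equal(cmp$fractures.x, cmp$fractures.y)
  expect_equal(cmp$cost_total, cmp$cost_millions, tolerance = 1e-9)
})

test_that("scenario grids are validated and the status quo added once", {
  mod <- get_model()
  res <- run_scenarios(mod, default_scenarios()[2:4, ])
  expect_setequal(res$scenarios$label,
                  c("status_quo", "1_50", "2_50", "3_50"))
  # empty grid runs the status quo only, with no net-benefit section
  only_sq <- run_scenarios(mod, default_scenarios()[0, ])
  expect_equal(unique(only_sq$burden$scenario), "status_quo")
  expect_equal(nrow(only_sq$net_benefit), 0)
  dup <- dplyr::bind_rows(intervention_spec("status_quo"),
                          intervention_spec("status_quo"))
  expect_error(run_scenarios(mod, dup), "exactly once")
})

test_that("tidy and glance expose burden, aggregate and net-benefit views", {
  res <- run_scenarios(get_model(), default_scenarios()[2:3, ])
  expect_s3_class(tidy(res), "tbl_df")
  expect_true(all(c("scenario", "country", "year", "fractures",
                    "cost_total") %in% names(tidy(res))))
  agg <- tidy(res, "aggregate")
  expect_false("country" %in% names(agg))
  nb <- tidy(res, "net_benefit")
  expect_setequal(unique(nb$scenario), c("1_50", "2_50"))
  g <- glance(res)
  expect_equal(nrow(g), 3)
  expect_true(all(c("delta_fractures", "pct_cost") %in% names(g)))
})

test_that("identical runs are deterministic and byte-identical on disk", {
  mod <- get_model()
  grid <- default_scenarios()[1:3, ]
  r1 <- run_scenarios(mod, grid)
  r2 <- run_scenarios(mod, grid)
  expect_identical(r1$burden, r2$burden)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario_outputs(r1, d1)
  write_scenario_outputs(r2, d2)
  for (f in c("burden.csv", "calibration.csv", "net_benefit.csv",
              "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("net-benefit cells render in the published delta (percent) format", {
  expect_equal(osteoburden:::fmt_delta(-217843, -17.591),
               "− 217,843 (− 17.6%)")
  expect_equal(osteoburden:::fmt_delta(-1850, -14.46, currency = TRUE),
               "− €1,850 (− 14.5%)")
  expect_equal(osteoburden:::fmt_delta(1000, 2.04), "+ 1,000 (+ 2.0%)")
})

test_that("rendered tables carry per-100k sub-rows and omit absent sections", {
  res_sq <- run_scenarios(get_model(), default_scenarios()[0, ])
  md <- render_tables(res_sq)
  expect_match(md, "Annual numbers of osteoporotic fractures")
  expect_match(md, "per 100,000", fixed = TRUE)
  expect_no_match(md, "Net benefits")
  res <- run_scenarios(get_model(), default_scenarios()[1:2, ])
  md2 <- render_tables(res)
  expect_match(md2, "Net benefits from status quo")
})

test_that("the config-driven pipeline runs end to end and rejects bad configs", {
  cfg_path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "profile:",
    "  at_risk_share: 0.30",
    "  at_risk_multiplier: 4.0",
    "scenarios:",
    "  - lever: adherence",
    "    improvement: 0.5",
    "seed: 7"
  ), cfg_path)
  out_dir <- withr::local_tempdir()
  res <- run_config(cfg_path, out_dir = out_dir)
  expect_s3_class(res, "scenario_result")
  expect_setequal(res$scenarios$label, c("status_quo", "2_50"))
  expect_true(file.exists(file.path(out_dir, "burden.csv")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  expect_equal(manifest$seed, 7)
  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("not_a_field: 1", bad)
  expect_error(run_config(bad), "unknown config field")
})

test_that("autoplot returns a faceted ggplot of the projection", {
  res <- run_scenarios(get_model(), default_scenarios()[1:2, ])
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_burden_projection(res), "ggplot")
})
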