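test_that("adherence lever removes the stated fraction of non-adherence", {
  expect_equal(improved_adherence_rate(0.40, 0.50), 0.70)
  expect_equal(improved_adherence_rate(0.40, 0), 0.40)
  expect_equal(improved_adherence_rate(0.40, 1), 1.00)
  expect_error(improved_adherence_rate(0.40, 1.5), "fraction")
})

test_that("assessment lever supports relative and gap interpretations", {
  expect_equal(improved_assessment_rate(0.25, 0.50), 0.375)
  expect_equal(improved_assessment_rate(0.25, 1.00), 0.50)
  expect_equal(improved_assessment_rate(0.25, 0.50, mode = "gap"), 0.625)
  expect_equal(improved_assessment_rate(0.9, 1.0), 1) # capped
})

test_that("treatment uptake follows the care-cascade formula", {
  # hand arithmetic: 0.22 + (0.375 - 0.25) * 0.57 * 0.33
  expect_equal(new_treatment_rate(0.22, 0.375, 0.25, 0.57, 0.33), 0.2435125)
  # zero assessment delta leaves any treatment rate untouched
  for (t in c(0, 0.1, 0.5, 1)) {
    expect_identical(new_treatment_rate(t, 0.3, 0.3, 0.5, 0.5), t)
  }
  expect_warning(out <- new_treatment_rate(0.9, 1.0, 0.25, 1.0, 1.0),
                 "clipped")
  expect_equal(out, 1.0)
  expect_error(new_treatment_rate(0.2, 0.2, 0.3, 0.5, 0.5),
               "never reduce")
})

test_that("apply_intervention composes the levers per country", {
  params <- read_country_params()
  be <- function(df) df[df$country == "BE", ]
  combined <- apply_intervention(params, intervention_spec("combined", 0.5))
  expect_equal(be(combined)$assessment_rate, 0.375)
  expect_equal(be(combined)$treatment_rate, 0.2435125)
  expect_equal(be(combined)$adherence_rate, 0.70)
  adh <- apply_intervention(params, intervention_spec("adherence", 0.5))
  expect_equal(adh$treatment_rate, params$treatment_rate)
  expect_equal(adh$assessment_rate, rep(0.25, nrow(params)))
  expect_equal(adh$adherence_rate, rep(0.70, nrow(params)))
})

test_that("zero improvement reproduces status-quo rates bit-exactly", {
  params <- read_country_params()
  sq <- tibble::tibble(country = params$country,
                       assessment_rate = 0.25,
                       treatment_rate = params$treatment_rate,
                       adherence_rate = 0.40)
  for (lever in c("assessment", "adherence", "combined", "status_quo")) {
    out <- apply_intervention(params, intervention_spec(lever, 0))
    expect_identical(out, sq)
  }
})

test_that("rates are monotone in f, bounded, and combined dominates each lever", {
  params <- read_country_params()
  fs <- c(0, 0.1, 0.25, 0.5, 0.75, 1)
  for (mode in c("relative", "gap")) {
    prev <- NULL
    for (f in fs) {
      a <- apply_intervention(params, intervention_spec("assessment", f,
                                                        assessment_mode = mode))
      d <- apply_intervention(params, intervention_spec("adherence", f))
      cb <- apply_intervention(params, intervention_spec("combined", f,
                                                         assessment_mode = mode))
      for (x in list(a, d, cb)) {
        expect_true(all(x$assessment_rate >= 0 & x$assessment_rate <= 1))
        expect_true(all(x$treatment_rate >= 0 & x$treatment_rate <= 1))
        expect_true(all(x$adherence_rate >= 0 & x$adherence_rate <= 1))
      }
      # combined dominates each single lever componentwise at equal f
      expect_true(all(cb$assessment_rate >= a$assessment_rate - 1e-12))
      expect_true(all(cb$treatment_rate >= a$treatment_rate - 1e-12))
      expect_true(all(cb$adherence_rate >= d$adherence_rate - 1e-12))
      if (!is.null(prev)) {
        expect_true(all(cb$assessment_rate >= prev$assessment_rate - 1e-12))
        expect_true(all(cb$treatment_rate >= prev$treatment_rate - 1e-12))
        expect_true(all(cb$adherence_rate >= prev$adherence_rate - 1e-12))
      }
      prev <- cb
    }
  }
})

test_that("scenario labels follow the published naming", {
  expect_equal(intervention_spec("assessment", 0.5)$label, "1_50")
  expect_equal(intervention_spec("adherence", 0.1)$label, "2_10")
  expect_equal(intervention_spec("combined", 1.0)$label, "3_100")
  expect_equal(intervention_spec("status_quo")$label, "status_quo")
  grid <- default_scenarios()
  expect_equal(sum(grid$label == "status_quo"), 1)
  expect_setequal(grid$label,
                  c("status_quo", "1_50", "2_50", "3_50", "1_10", "2_10",
                    "3_10", "1_100", "2_100", "3_100"))
})
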