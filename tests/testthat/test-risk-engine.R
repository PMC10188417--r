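test_that("FRAX-like risk returns the baselines exactly at the reference point", {
  p <- risk_function_params()
  out <- frax_like_risk(70, 0, rep(0, 6), p)
  expect_equal(unlist(out), p$base_rate, ignore_attr = TRUE)
})

test_that("FRAX-like risk rises with age and with falling T-score", {
  young <- frax_like_risk(70, -1, rep(0, 6))
  old <- frax_like_risk(80, -1, rep(0, 6))
  expect_true(all(old > young))
  dense <- frax_like_risk(75, 0, rep(0, 6))
  sparse <- frax_like_risk(75, -2.5, rep(0, 6))
  expect_true(all(sparse > dense))
  expect_error(frax_like_risk(69, 0, rep(0, 6)), "70")
})

test_that("FRAX-like risk matches an independent scalar re-evaluation", {
  p <- risk_function_params()
  age <- 78; ts <- -2.2
  flags <- c(1, 0, 1, 0, 0, 1) # prior fracture, smoking, alcohol
  got <- frax_like_risk(age, ts, flags, p)
  for (ft in fracture_types()) {
    h <- -log(1 - p$base_rate[[ft]])
    h <- h * exp(p$age_slope[[ft]] * (age - 70))
    h <- h * p$gradient_per_sd[[ft]]^(-ts)
    h <- h * p$crf_multipliers["prior_fracture", ft] *
      p$crf_multipliers["smoking", ft] * p$crf_multipliers["alcohol", ft]
    expect_equal(got[[ft]], 1 - exp(-h))
  }
  expect_true(all(unlist(got) >= 0 & unlist(got) <= 1))
})

test_that("population risk obeys its no-treatment and full-treatment identities", {
  base <- c(hip = 0.01, vertebral = 0.008, nhnv = 0.03)
  rr <- c(hip = 0.6, vertebral = 0.45, nhnv = 0.8)
  pr <- risk_profile(base, at_risk_share = 0.3, at_risk_multiplier = 4)
  untreated <- population_risk(pr, management_rates(0.25, 0, 0.4), rr)
  expect_equal(untreated, base * (0.3 * 4 + 0.7), ignore_attr = TRUE)
  # single stratum, everyone treated and adherent, RR 0.5 -> exactly half
  one <- risk_profile(base, at_risk_share = 0, at_risk_multiplier = 1)
  halved <- population_risk(one, management_rates(0.25, 1, 1),
                            c(hip = 0.5, vertebral = 0.5, nhnv = 0.5))
  expect_equal(halved, base / 2, ignore_attr = TRUE)
})

test_that("population risk equals exhaustive cell enumeration", {
  pr <- risk_profile(c(hip = 0.01, vertebral = 0.01, nhnv = 0.01),
                     at_risk_share = 0.3, at_risk_multiplier = 4)
  got <- population_risk(pr, management_rates(0.25, 0.2, 0.4),
                         c(hip = 0.62, vertebral = 0.62, nhnv = 0.62))
  expect_equal(unname(got["hip"]), 0.017784) # frozen from the oracle below
  expect_equal(unname(got["hip"]),
               enum_pop_risk(0.01, 0.3, 4, 0.2, 0.4, 0.62))
  # randomized cases, including treatment spillover beyond the at-risk stratum
  withr::with_seed(11, {
    for (i in 1:25) {
      base <- runif(3, 0.001, 0.05)
      names(base) <- fracture_types()
      share <- runif(1, 0.05, 0.6)
      mult <- runif(1, 1, 6)
      tau <- runif(1, 0, 0.9)
      alpha <- runif(1, 0, 1)
      rr <- runif(3, 0.3, 1)
      names(rr) <- fracture_types()
      if (max(base) * mult > 1) next
      pr_i <- risk_profile(base, share, mult)
      got_i <- population_risk(pr_i, management_rates(0.25, tau, alpha), rr)
      want <- vapply(fracture_types(), function(ft)
        enum_pop_risk(base[[ft]], share, mult, tau, alpha, rr[[ft]]),
        numeric(1))
      expect_equal(got_i, want, tolerance = 1e-12)
    }
  })
})

test_that("risk is monotone in treatment, adherence and efficacy, and RR=1 is neutral", {
  base <- c(hip = 0.012, vertebral = 0.009, nhnv = 0.035)
  rr <- c(hip = 0.6, vertebral = 0.45, nhnv = 0.8)
  pr <- risk_profile(base)
  p0 <- population_risk(pr, management_rates(0.25, 0.1, 0.4), rr)
  p_tau <- population_risk(pr, management_rates(0.25, 0.25, 0.4), rr)
  p_adh <- population_risk(pr, management_rates(0.25, 0.1, 0.7), rr)
  p_both <- population_risk(pr, management_rates(0.25, 0.25, 0.7), rr)
  expect_true(all(p_tau <= p0 & p_adh <= p0))
  expect_true(all(p_both <= pmin(p_tau, p_adh)))
  neutral <- population_risk(pr, management_rates(0.25, 0.8, 1),
                             c(hip = 1, vertebral = 1, nhnv = 1))
  expect_equal(neutral, population_risk(pr, management_rates(0.25, 0, 0.4),
                                        c(hip = 1, vertebral = 1, nhnv = 1)))
  # partial efficacy for non-adherent women lowers risk further
  p_eff <- population_risk(pr, management_rates(0.25, 0.25, 0.4), rr,
                           nonadherent_efficacy = 0.5)
  p_noeff <- population_risk(pr, management_rates(0.25, 0.25, 0.4), rr)
  expect_true(all(p_eff <= p_noeff))
})

test_that("probability capping clips to [0, 1] with a warning", {
  expect_warning(out <- cap_probabilities(c(0.5, 0.2, 1.3)), "clipped")
  expect_equal(out, c(0.5, 0.2, 1.0))
  expect_silent(expect_equal(cap_probabilities(c(0.1, 0.9)), c(0.1, 0.9)))
  expect_warning(out2 <- cap_probabilities(-0.2), "clipped")
  expect_equal(out2, 0)
})
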