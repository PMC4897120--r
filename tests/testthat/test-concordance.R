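test_that("twin-state probabilities form a binomial partition", {
  s0 <- twin_state_probabilities(0, pf)
  expect_equal(unlist(s0[c("p_ss", "p_sx", "p_xx")]),
               c(p_ss = 0, p_sx = 0, p_xx = 1))
  t <- seq(0, 300, by = 1)
  s <- twin_state_probabilities(t, pf)
  expect_equal(s$p_ss + s$p_sx + s$p_xx, rep(1, length(t)),
               tolerance = 1e-12)
  expect_true(all(s$p_ss >= 0 & s$p_sx >= 0 & s$p_xx >= 0))
  # consistency with the prevalence
  expect_equal(s$p_ss, susceptible_prevalence(t, pf)^2, tolerance = 1e-12)
})

test_that("twin-state triple at 40 months matches the printed percentages", {
  s <- twin_state_probabilities(40, pf)
  expect_equal(round(c(s$p_ss, s$p_sx, s$p_xx), 3), c(0.412, 0.460, 0.128))
})

test_that("MZ concordance curve has the stated shape and landmarks", {
  expect_equal(mz_concordance(0, pf), 0)
  t <- seq(0, 400, by = 0.5)
  cm <- mz_concordance(t, pf)
  expect_true(all(diff(cm) >= 0))
  expect_equal(mz_concordance(1e6, pf), 1, tolerance = 1e-9)
  # definition consistency with the state probabilities
  s <- twin_state_probabilities(t[-1], pf)
  expect_equal(mz_concordance(t[-1], pf), s$p_ss / (s$p_ss + s$p_sx),
               tolerance = 1e-12)
  # 50% concordance at 42 months; 96% by 123 months (female set)
  t_half <- uniroot(function(x) mz_concordance(x, pf) - 0.5, c(1, 300),
                    tol = 1e-10)$root
  expect_equal(round(t_half), 42)
  expect_equal(round(mz_concordance(123, pf), 2), 0.96)
})

test_that("MZ concordance matches a Monte-Carlo pair simulation", {
  set.seed(101)
  n <- 1e6
  ps <- susceptible_prevalence(60, pf)
  a <- runif(n) < ps
  b <- runif(n) < ps
  asc <- a | b
  emp <- sum(a & b) / sum(asc)
  se <- sqrt(emp * (1 - emp) / sum(asc))
  expect_lt(abs(emp - mz_concordance(60, pf)), 3 * se)
})

test_that("concordance-prevalence inversion reproduces 41/60 -> 82/101", {
  expect_equal(prevalence_from_mz_concordance(41 / 60), 82 / 101)
  expect_equal(prevalence_from_mz_concordance(0), 0)
  expect_equal(prevalence_from_mz_concordance(1 / 3), 1 / 2)
  expect_error(prevalence_from_mz_concordance(1), "\\[0, 1\\)")
  expect_error(prevalence_from_mz_concordance(-0.1), "\\[0, 1\\)")
  # round trip through the model curve
  t0 <- c(12, 42, 90, 200)
  expect_equal(prevalence_from_mz_concordance(mz_concordance(t0, pf)),
               susceptible_prevalence(t0, pf), tolerance = 1e-12)
})

test_that("age-cohort inversion gives 55 months for the female set", {
  expect_equal(round(age_for_observed_mz_concordance(41 / 60, pf)), 55)
  # male set lands elsewhere: the documented male/female discrepancy
  expect_equal(age_for_observed_mz_concordance(41 / 60, pm), 57.2,
               tolerance = 0.2 / 57.2)
  # round trip for arbitrary ages
  for (t0 in c(20, 55, 110)) {
    expect_equal(age_for_observed_mz_concordance(mz_concordance(t0, pf), pf),
                 t0, tolerance = 1e-6 / t0)
  }
})

test_that("DZ concordance saturates at the inherited susceptibility", {
  t <- seq(0, 500, by = 1)
  expect_equal(dz_concordance(t, 0, pf), rep(0, length(t)))
  cd <- dz_concordance(t, 0.188, pf)
  expect_true(all(diff(cd) >= 0))
  expect_equal(dz_concordance(1e7, 0.188, pf), 0.188, tolerance = 1e-9)
  # always below the MZ curve for s < 1
  expect_true(all(cd[-1] < mz_concordance(t[-1], pf)))
  expect_error(dz_concordance(10, 1.2, pf), "\\[0, 1\\]")
})

test_that("DZ concordance matches a Monte-Carlo pair simulation", {
  set.seed(202)
  n <- 1e6
  s <- 0.188
  ps <- susceptible_prevalence(55, pf)
  b_susc <- runif(n) < s
  a <- runif(n) < ps
  b <- b_susc & runif(n) < ps
  asc <- a | b
  emp <- sum(a & b) / sum(asc)
  se <- sqrt(emp * (1 - emp) / sum(asc))
  expect_lt(abs(emp - dz_concordance(55, s, pf)), 3 * se)
  # at this age the curve sits below its saturation value
  expect_lt(dz_concordance(55, s, pf), s)
})

test_that("inherited susceptibility estimators behave as specified", {
  expect_equal(round(s_inher_from_observed(49 / 260), 3), 0.188)
  # model-inverse at saturation coincides with the direct assignment
  expect_equal(s_inher_from_observed(0.3, p_s_obs = 1,
                                     mode = "model-inverse"), 0.3)
  # solving the reconstructed curve at the 2014 prevalence gives ~0.242
  expect_equal(s_inher_from_observed(0.188, p_s_obs = 0.812,
                                     mode = "model-inverse"),
               0.242, tolerance = 1e-3 / 0.242)
  # round trip against the forward curve
  s_true <- 0.35
  cd <- dz_concordance(70, s_true, pf)
  expect_equal(s_inher_from_observed(cd,
                 p_s_obs = susceptible_prevalence(70, pf),
                 mode = "model-inverse"), s_true, tolerance = 1e-9)
  expect_error(s_inher_from_observed(0.9, p_s_obs = 0.5,
                                     mode = "model-inverse"), "no inherited")
})

test_that("discrete expected concordance averages the curve", {
  expect_equal(expected_mz_concordance_discrete(60, pf),
               mz_concordance(60, pf))
  expect_equal(expected_mz_concordance_discrete(c(12, 120), pf),
               mean(mz_concordance(c(12, 120), pf)), tolerance = 1e-12)
  expect_equal(expected_mz_concordance_discrete(c(12, 120), pf,
                                                counts = c(3, 1)),
               (3 * mz_concordance(12, pf) + mz_concordance(120, pf)) / 4,
               tolerance = 1e-12)
  expect_error(expected_mz_concordance_discrete(numeric(0), pf), "nonempty")
})

test_that("onset-weighted expected concordance: closed form vs quadrature", {
  # the headline limit: 2 ln 2 - 1
  expect_equal(expected_mz_concordance_onset_weighted(Inf, pf),
               2 * log(2) - 1)
  expect_equal(round(expected_mz_concordance_onset_weighted(Inf, pf), 5),
               0.38629)
  for (t_o in c(5, 10, 20, 33, 42, 55, 80, 124, 200, 1000)) {
    expect_lt(abs(expected_mz_concordance_onset_weighted(t_o, pf) -
                  expected_mz_concordance_onset_weighted(t_o, pf,
                                                         "quadrature")),
              1e-8)
    expect_lt(abs(expected_mz_concordance_onset_weighted(t_o, pm) -
                  expected_mz_concordance_onset_weighted(t_o, pm,
                                                         "quadrature")),
              1e-8)
  }
  # vanishes near the origin
  expect_lt(expected_mz_concordance_onset_weighted(0.01, pf), 1e-3)
  expect_error(expected_mz_concordance_onset_weighted(0, pf), "positive")
})

test_that("large discrete cohorts converge to the closed form", {
  set.seed(7)
  t_o <- 240
  u <- runif(1e5, 0, susceptible_prevalence(t_o, pf))
  ages <- onset_quantile(u, pf)  # ages distributed as the truncated onset law
  expect_equal(expected_mz_concordance_discrete(ages, pf),
               expected_mz_concordance_onset_weighted(t_o, pf),
               tolerance = 0.005 / 0.3)
})

test_that("the saturation limit is distribution-free", {
  # exponential onset law instead of the multimutation CDF
  lam <- 0.05
  val <- integrate(function(t) {
    f <- 1 - exp(-lam * t)
    (f / (2 - f)) * lam * exp(-lam * t)
  }, 0, Inf, rel.tol = 1e-12)$value
  expect_equal(val, 2 * log(2) - 1, tolerance = 1e-6)
  # and a Weibull-like law
  val2 <- integrate(function(t) {
    f <- 1 - exp(-(t / 30)^2)
    (f / (2 - f)) * (2 * t / 900) * exp(-(t / 30)^2)
  }, 0, Inf, rel.tol = 1e-12)$value
  expect_equal(val2, 2 * log(2) - 1, tolerance = 1e-6)
})

test_that("clock-rate calibration reproduces the Canadian medians", {
  med <- onset_quantile(0.5, pm)
  expect_equal(clock_rate_for_median(med, pm), 1, tolerance = 1e-9)
  expect_equal(clock_rate_for_median(39, pm), 0.865,
               tolerance = 0.002 / 0.865)
  expect_equal(clock_rate_for_median(55, pm), 0.613,
               tolerance = 0.002 / 0.613)
  # the scaling law forces the ratio 39/55, whatever the shape parameters
  expect_equal(clock_rate_for_median(55, pm) / clock_rate_for_median(39, pm),
               39 / 55, tolerance = 1e-9)
  # calibrated curve really has the target median
  r55 <- clock_rate_for_median(55, pm)
  expect_equal(onset_quantile(0.5, with_clock_rate(pm, r55)), 55,
               tolerance = 1e-8)
  expect_error(clock_rate_for_median(-3, pm), "positive")
})
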