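test_that("Terzaghi series: limits, classical values, truncation", {
  prob <- terzaghi_problem(L = 1, c_v = 0.5, load = 1, n_terms = 100)

  # full consolidation
  expect_lt(max(abs(terzaghi_pressure(c(0, 0.3, 0.9), 1e4, prob))), 1e-12)
  # undrained instant response in the interior
  prob_hi <- terzaghi_problem(1, 0.5, 1, n_terms = 2000)
  expect_equal(terzaghi_pressure(0.2, 2e-6, prob_hi), 1, tolerance = 1e-2)
  # drained boundary
  expect_equal(terzaghi_pressure(1, 0.05, prob), 0, tolerance = 1e-12)

  expect_equal(terzaghi_consolidation(0.5), 0.7639, tolerance = 1e-3)
  expect_equal(terzaghi_consolidation(0.1), 0.357, tolerance = 2e-3)

  # doubling the truncation order changes nothing at Tv >= 0.1
  u1 <- terzaghi_consolidation(c(0.1, 0.5, 1), n_terms = 100)
  u2 <- terzaghi_consolidation(c(0.1, 0.5, 1), n_terms = 200)
  expect_lt(max(abs(u1 - u2)), 1e-10)
})

test_that("kinetics reference preserves fixed points and peak structure", {
  prm <- reference_parameters("local-1d")
  tg <- seq(0, 150, by = 0.5)

  none <- kinetics_reference(0, 0.003, prm, tg)
  expect_true(all(none$c_p == 0))
  expect_equal(none$c_l, rep(0.003, length(tg)), tolerance = 1e-12)

  # reference initial data: c_p rises then falls with one interior maximum
  ref <- kinetics_reference(0.001, 0.003, prm, tg)
  i <- which.max(ref$c_p)
  expect_gt(i, 1)
  expect_lt(i, length(tg))
  expect_true(all(diff(ref$c_p[1:i]) > 0))
  expect_true(all(diff(ref$c_p[i:length(tg)]) < 0))
  # leukocytes are nondecreasing (no decay in the model)
  expect_true(all(diff(ref$c_l) >= 0))
})

test_that("baseline exchange balance is small and solvable for sigma0", {
  prm <- reference_parameters("local-1d")
  bb <- baseline_balance(prm)
  expect_equal(bb, 7.8e-8 * 86400, tolerance = 2e-2)
  expect_lt(abs(bb), 0.002 * prm$q0)

  # contrived sigma0 that balances filtration and drainage exactly
  Cf0 <- prm$S_over_V * prm$L_p0
  sigma_star <- (Cf0 * prm$P_c - prm$q0) / (Cf0 * (prm$pi_c - prm$pi_i))
  prm2 <- set_parameter(prm, "sigma0", sigma_star)
  expect_equal(baseline_balance(prm2), 0, tolerance = 1e-12)
})

test_that("the oracle suite runs and reports all three checks", {
  tab <- verify_solver(quiet = TRUE)
  expect_s3_class(tab, "data.frame")
  expect_equal(tab$check, c("terzaghi", "kinetics-ode-limit", "rest-state"))
  expect_true(all(tab$pass))
})
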