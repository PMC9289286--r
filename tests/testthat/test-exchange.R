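prm <- reference_parameters("local-1d")

test_that("capillary conductivity and reflection coefficient respond to pathogen", {
  # baseline (S/V) * L_p0 printed per second: 174 * 3.6e-8 = 6.264e-6
  expect_equal(capillary_conductivity(0, prm), 6.264e-6 * 86400,
               tolerance = 1e-12)
  expect_equal(capillary_conductivity(0.001, prm),
               11 * capillary_conductivity(0, prm))
  p0c <- set_parameter(prm, "c_bp", 0)
  expect_equal(capillary_conductivity(5, p0c),
               capillary_conductivity(0, p0c))

  expect_equal(reflection_coefficient(0, prm), 0.91)
  expect_equal(reflection_coefficient(0.001, prm), 0.91 / 11)
  expect_lt(reflection_coefficient(1e3, prm), 1e-6)

  expect_error(capillary_conductivity(-1e-9, prm), "nonnegative")
  expect_error(reflection_coefficient(-1, prm), "nonnegative")
})

test_that("lymphatic drainage follows the clamped Hill law", {
  expect_equal(lymphatic_flow(prm$p0, prm), prm$q0)
  expect_equal(lymphatic_flow(prm$p0 - 5, prm), prm$q0)  # clamp below rest
  expect_equal(lymphatic_flow(prm$p0 + prm$k_m, prm),
               prm$q0 * (1 + prm$v_max / 2))              # half saturation
  expect_equal(lymphatic_flow(1e9, prm), prm$q0 * (1 + prm$v_max),
               tolerance = 1e-6)
})

test_that("fluid exchange is near-homeostatic at rest and responds to infection", {
  rest <- fluid_exchange(0, 0, prm)
  expect_equal(rest$total, rest$capillary_flow - rest$lymph_flow)
  expect_lt(abs(rest$total), 0.002 * prm$q0)

  infl <- fluid_exchange(0, 0.001, prm)
  expect_gt(infl$total, 0)   # inflammation produces net filtration

  # at capillary pressure the filtration term collapses to the residual
  # oncotic pull -C_f0 sigma0 (pi_c - pi_i), small against drainage
  hi <- fluid_exchange(prm$P_c, 1, prm)
  expect_lt(hi$capillary_flow, 0)
  expect_lt(abs(hi$capillary_flow), 0.01 * abs(hi$lymph_flow))
  expect_lt(hi$total, 0)
})

test_that("exchange is decreasing in pressure and increasing in pathogen", {
  ps <- seq(0, 20, by = 0.25)
  tot <- vapply(ps, function(p) fluid_exchange(p, 5e-4, prm)$total,
                numeric(1))
  expect_true(all(diff(tot) < 0))

  cps <- seq(0, 0.02, by = 5e-4)
  tot2 <- vapply(cps, function(cc) fluid_exchange(5, cc, prm)$total,
                 numeric(1))
  expect_true(all(diff(tot2) > 0))
})

test_that("reaction kinetics have the zero-concentration fixed points", {
  expect_equal(pathogen_reaction(0.2, 0, 0.003, prm), 0)
  expect_equal(leukocyte_reaction(0, 0.003, prm), 0)
  expect_equal(leukocyte_reaction(0.001, 0, prm), 0)

  # exact balance of growth and phagocytosis
  cl_star <- prm$gamma_p / prm$lambda_lp
  expect_equal(pathogen_reaction(0.2, 0.5, cl_star, prm), 0)

  expect_equal(pathogen_reaction(0.2, 0.001, 0.003, prm),
               0.2 * (0.09 - 1.5 * 0.003) * 0.001)
  expect_equal(pathogen_reaction(0.2, 0.001, 0.003, prm), 1.71e-5,
               tolerance = 1e-9)
  expect_equal(leukocyte_reaction(0.001, 0.003, prm), 2.1 * 0.001 * 0.003)

  expect_error(pathogen_reaction(0, 0.001, 0.003, prm), "phi_f")
  expect_error(pathogen_reaction(0.2, -1, 0.003, prm), "nonnegative")
})
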