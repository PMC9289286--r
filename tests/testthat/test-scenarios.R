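test_that("scenario construction is pure and matches the reference setup", {
  sc <- build_scenario("local-1d")
  expect_equal(sc$L, 8)
  expect_equal(sc$infected_interval, c(3.8, 4.2))
  expect_equal(sc$c_p_init, 0.001)
  expect_equal(sc$c_l_init, 0.003)
  expect_equal(sc$phi0, 0.2)
  expect_identical(sc, build_scenario("local-1d"))

  dif <- build_scenario("diffuse-1d")
  expect_equal(dif$infected_interval, sc$infected_interval)
  expect_equal(dif$params$d_p, 5e-3)

  expect_error(build_scenario("global-1d"))
})

test_that("the initial pathogen field is confined to the infected region", {
  sc <- build_scenario("diffuse-1d")
  mesh <- mesh_1d(8, 400)
  s0 <- initial_state(sc, mesh)
  inside <- mesh$nodes >= 3.8 & mesh$nodes <= 4.2
  expect_true(all(s0$c_p[inside] == 0.001))
  expect_true(all(s0$c_p[!inside] == 0))
  expect_true(all(s0$c_l == 0.003))
  expect_true(all(s0$u == 0) && all(s0$p == 0))
})

test_that("parameter overrides propagate into the resolved set", {
  sc <- build_scenario("local-1d", overrides = list(gamma_p = 0.18))
  expect_equal(sc$params$gamma_p, 0.18)
  sc2 <- build_scenario("local-1d", overrides = list(E = 90))
  expect_equal(sc2$params$mu_s, 90 / 2.7, tolerance = 1e-12)
})

test_that("one-at-a-time scaling touches exactly one primitive parameter", {
  base <- reference_parameters("local-1d")
  derived <- c("mu_s", "lambda_s")
  for (nm in c("gamma_p", "d_p", "lambda_lp", "E")) {
    scaled <- set_parameter(base, nm, 2 * base[[nm]])
    for (field in names(base)) {
      if (field == nm || (nm == "E" && field %in% derived)) {
        expect_false(identical(scaled[[field]], base[[field]]))
      } else {
        expect_identical(scaled[[field]], base[[field]])
      }
    }
  }
})

test_that("the identity factor reproduces a plain run", {
  cfg <- coarse_config(t_final = 2, dt = 0.25, n_elems = 20)
  base <- build_scenario("local-1d")
  oat <- oat_sensitivity(base, "gamma_p", factors = 1, config = cfg)
  plain <- run_simulation(base, cfg)
  expect_equal(oat[[1]]$summary, plain$summary, tolerance = 1e-14)
})

test_that("panel reproduction guards its inputs", {
  expect_error(fig_sensitivity_panel("q0"), "oat_sensitivity")
  expect_error(fig_sensitivity_panel("gamma_p", factors = numeric(0)),
               "nonempty")
  expect_error(oat_sensitivity(build_scenario("local-1d"), "nonesuch"),
               "unknown parameter")
})
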