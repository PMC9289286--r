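test_that("Lame parameters follow the closed forms and invert", {
  lam <- lame_from_elastic(60, 0.35)
  expect_equal(lam[["mu_s"]], 60 / (2 * 1.35), tolerance = 1e-12)
  expect_equal(lam[["mu_s"]], 22.2222, tolerance = 1e-4)
  expect_equal(lam[["lambda_s"]], 51.8519, tolerance = 1e-4)

  lam0 <- lame_from_elastic(60, 0)
  expect_equal(unname(lam0), c(30, 0))

  expect_error(lame_from_elastic(60, 0.5), "incompressible|invalid")
  expect_error(lame_from_elastic(60, -0.1), "invalid|Poisson")
  expect_error(lame_from_elastic(-5, 0.3), "positive")

  # round-trip over a grid
  for (E in c(1, 45, 300)) {
    for (nu in c(0.05, 0.3, 0.49)) {
      l <- lame_from_elastic(E, nu)
      back <- elastic_from_lame(l[["mu_s"]], l[["lambda_s"]])
      expect_equal(back[["E"]], E, tolerance = 1e-12)
      expect_equal(back[["nu"]], nu, tolerance = 1e-12)
    }
  }
})

test_that("reference presets carry the tabulated values", {
  loc <- reference_parameters("local-1d")
  expect_equal(loc$gamma_p, 9.0e-2)
  expect_equal(loc$lambda_pl, 2.1)
  expect_equal(loc$d_p, 1e-3)
  expect_equal(loc$d_l, 5e-2)

  dif <- reference_parameters("diffuse-1d")
  expect_equal(dif$d_p, 5e-3)
  expect_equal(dif$gamma_p, 3e-2)
  expect_equal(dif$lambda_pl, 1e-1)

  for (preset in c("local-1d", "diffuse-1d", "local-3d", "diffuse-3d")) {
    p <- reference_parameters(preset)
    expect_equal(p$lambda_lp, 1.5)
    expect_equal(p$sigma0, 0.91)
    expect_equal(p$phi0, 0.2)
    expect_equal(p$c_bp, 1e4)
    expect_equal(p$n_hill, 1)
    expect_equal(p$v_max, 200)
  }

  expect_error(reference_parameters("local-2d"), "local-1d")
})

test_that("unit normalisation converts to the day/mmHg system and is idempotent", {
  p <- reference_parameters("local-1d")
  expect_equal(p$q0, 6.82e-5 * 86400)          # 5.89248 per day
  expect_equal(p$q0, 5.89248, tolerance = 1e-9)
  expect_equal(p$E, 60 / 1.33322, tolerance = 1e-9)
  expect_equal(p$E, 45.0, tolerance = 1e-3)
  expect_equal(p$L_p0, 3.6e-8 * 86400)
  expect_equal(p$kappa0, 2.5e-7 * 86400)

  # idempotence: all tags are internal after construction
  p2 <- normalize_units(p)
  expect_identical(unclass(p2)[], unclass(p)[])
})

test_that("parameter validation rejects out-of-domain values", {
  p <- reference_parameters("local-1d")
  expect_error(set_parameter(p, "nu", 0.5), "nu|incompressible")
  expect_error(set_parameter(p, "phi0", 1.2), "phi0")
  expect_error(set_parameter(p, "sigma0", 1.5), "sigma0")
  expect_error(set_parameter(p, "nonesuch", 1), "unknown parameter")

  # E update re-derives the Lame parameters
  p2 <- set_parameter(p, "E", 2 * p$E)
  expect_equal(p2$mu_s, 2 * p$mu_s, tolerance = 1e-12)
  expect_equal(p2$lambda_s, 2 * p$lambda_s, tolerance = 1e-12)
})

test_that("parameter sets round-trip through the key:value text format", {
  p <- reference_parameters("diffuse-1d")
  f <- tempfile(fileext = ".cfg")
  on.exit(unlink(f))
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_equal(unclass(q)[names(p)], unclass(p)[], tolerance = 1e-15,
               ignore_attr = TRUE)
})
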