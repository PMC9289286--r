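# Structural checks of the discrete residual and the Newton stepper.

test_that("the rest state is an exact residual root when exchange is off", {
  sc <- build_scenario("local-1d", c_p_init = 0,
                       flags = list(exchange = FALSE))
  mesh <- mesh_1d(8, 40)
  s0 <- initial_state(sc, mesh)
  r <- assemble_residual(s0, s0, dt = 0.1, sc$params, mesh, sc)
  expect_lt(max(abs(r)), 1e-14)
})

test_that("with state_new = state_old the residual is independent of dt", {
  # backward-Euler structure: all time-derivative blocks vanish
  sc <- build_scenario("local-1d", flags = list(exchange = FALSE,
                                                reactions = FALSE))
  mesh <- mesh_1d(8, 30)
  s <- initial_state(sc, mesh)
  x <- mesh$nodes
  s$u <- 1e-3 * sin(pi * x / 8) * x / 8
  s$p <- 0.5 * cos(pi * x / 8)
  s$phi_f <- 0.2 + 1e-3 * sin(2 * pi * x / 8)
  s$c_p <- 1e-3 * exp(-(x - 4)^2)
  r1 <- assemble_residual(s, s, dt = 0.1, sc$params, mesh, sc)
  r2 <- assemble_residual(s, s, dt = 1e6, sc$params, mesh, sc)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("the residual flags non-finite fields by name", {
  sc <- build_scenario("local-1d")
  mesh <- mesh_1d(8, 10)
  s <- initial_state(sc, mesh)
  s$p[3] <- NaN
  expect_error(assemble_residual(s, s, 0.1, sc$params, mesh, sc),
               "non-finite.*p")
})

test_that("Newton converges immediately from an exact root and from nearby", {
  sc <- build_scenario("local-1d", c_p_init = 0,
                       flags = list(exchange = FALSE))
  mesh <- mesh_1d(8, 40)
  s0 <- initial_state(sc, mesh)
  cfg <- solver_config(n_elems = 40)
  s1 <- newton_step(s0, s0, dt = 0.1, sc$params, mesh, sc, cfg)
  expect_equal(s1$u, s0$u)
  expect_equal(s1$phi_f, s0$phi_f)

  # perturbed guess converges back to the residual tolerance
  sg <- s0
  sg$p <- s0$p + 1e-3
  sg$phi_f <- s0$phi_f + 1e-3 * sin(mesh$nodes)
  s2 <- newton_step(sg, s0, dt = 0.1, sc$params, mesh, sc, cfg)
  r <- assemble_residual(s2, s0, 0.1, sc$params, mesh, sc)
  expect_lt(sqrt(sum(r^2)), cfg$newton_tol)
})

test_that("non-convergence raises an error reporting the residual norm", {
  sc <- build_scenario("local-1d")
  mesh <- mesh_1d(8, 20)
  s0 <- initial_state(sc, mesh)
  sg <- s0
  sg$u <- 0.3 * sin(pi * mesh$nodes / 16)
  cfg <- solver_config(newton_max_iter = 1, newton_tol = 1e-14)
  expect_error(newton_step(sg, s0, 0.1, sc$params, mesh, sc, cfg),
               "residual norm")
})

test_that("essential and natural boundary conditions hold along a run", {
  traj <- cached_run("local-short",
                     build_scenario("local-1d"),
                     coarse_config(t_final = 10))
  prm <- traj$params
  h <- traj$mesh$h
  n <- traj$mesh$n_elems
  for (s in traj$snapshots[-1]) {
    expect_lt(abs(s$u[1]), 1e-14)                     # u(0) = 0, strong
    Fn <- 1 + (s$u[n + 1] - s$u[n]) / h[n]            # last element
    pm <- 0.5 * (s$p[n] + s$p[n + 1])
    S <- effective_stress_1d(Fn, prm$mu_s, prm$lambda_s) - prm$alpha * pm
    expect_lt(abs(S), 1e-5)                           # traction-free at L
  }
})

test_that("closed-system runs conserve material fluid and species content", {
  sc <- build_scenario("local-1d",
                       flags = list(exchange = FALSE, reactions = FALSE))
  cfg <- coarse_config(t_final = 20, dt = 0.25, n_elems = 80,
                       snapshot_every = 5)
  traj <- run_simulation(sc, cfg)
  w <- traj$mesh$w
  content <- function(s, f) sum(w * s$phi_f * s[[f]])
  fluid0 <- sum(w * traj$snapshots[[1]]$phi_f)
  cp0 <- content(traj$snapshots[[1]], "c_p")
  cl0 <- content(traj$snapshots[[1]], "c_l")
  for (s in traj$snapshots[-1]) {
    expect_equal(sum(w * s$phi_f), fluid0, tolerance = 1e-8)
    expect_equal(content(s, "c_p"), cp0, tolerance = 1e-6)
    expect_equal(content(s, "c_l"), cl0, tolerance = 1e-6)
  }
})

test_that("the saturation constraint holds at every snapshot", {
  traj <- cached_run("local-short",
                     build_scenario("local-1d"),
                     coarse_config(t_final = 10))
  h <- traj$mesh$h
  n <- traj$mesh$n_elems
  tol <- 10 * traj$config$newton_tol
  for (s in traj$snapshots) {
    F <- 1 + diff(s$u) / h
    Jn <- c(F[1], 0.5 * (F[-1] + F[-n]), F[n])
    expect_lt(max(abs(Jn - s$phi_f - (1 - 0.2))), tol)
  }
})

test_that("simulations are deterministic", {
  sc <- build_scenario("local-1d")
  cfg <- coarse_config(t_final = 5)
  a <- run_simulation(sc, cfg)
  b <- run_simulation(sc, cfg)
  expect_identical(a$summary, b$summary)
})

test_that("concentrations stay nonnegative across the infection front", {
  traj <- cached_run("local-short",
                     build_scenario("local-1d"),
                     coarse_config(t_final = 10))
  for (s in traj$snapshots) {
    expect_true(all(s$c_p >= 0))
    expect_true(all(s$c_l >= 0))
    expect_true(all(s$phi_f > 0 & s$phi_f < 1))
  }
})
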