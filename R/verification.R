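# Independent oracles used to validate the solver: the classical Terzaghi
# consolidation series, a high-accuracy integration of the homogeneous
# immune kinetics, and the capillary-lymphatic baseline balance.

#' Define a 1D consolidation benchmark problem
#'
#' A poroelastic column of length `L` with a drained, loaded end at
#' `x = L` and an impermeable fixed end at `x = 0`, under a step load.
#' The consolidation coefficient follows from the Darcy mobility, the
#' resting fluid fraction carried by the flux, and the 1D constrained
#' modulus: `c_v = (kappa0/mu_f) * phi0 * (lambda_s + 2 mu_s)`.
#'
#' @param L Column length (cm).
#' @param c_v Consolidation coefficient (cm^2/day).
#' @param load Applied compressive load magnitude (mmHg).
#' @param n_terms Series truncation order (>= 50 recommended).
#' @return Object of class `terzaghi_problem`.
#' @export
terzaghi_problem <- function(L, c_v, load, n_terms = 100) {
  stopifnot(L > 0, c_v > 0, n_terms >= 1)
  structure(list(L = L, c_v = c_v, load = load,
                 n_terms = as.integer(n_terms)),
            class = "terzaghi_problem")
}

#' Closed-form excess pore pressure of 1D consolidation
#'
#' Fourier series solution for a step load with drainage at `x = L` and an
#' impermeable boundary at `x = 0`:
#' \deqn{p(x,t) = \sum_m \frac{2 q}{M} \sin(M \zeta) e^{-M^2 T_v},}
#' with \eqn{M = \pi(2m+1)/2}, \eqn{\zeta = (L-x)/L} and
#' \eqn{T_v = c_v t / L^2}.
#'
#' @param x Position(s) in `[0, L]` (cm).
#' @param t Time (day), >= 0.
#' @param prob A [terzaghi_problem()].
#' @return Excess pore pressure (mmHg).
#' @export
terzaghi_pressure <- function(x, t, prob) {
  stopifnot(t >= 0, all(x >= 0), all(x <= prob$L))
  Tv <- prob$c_v * t / prob$L^2
  zeta <- (prob$L - x) / prob$L
  m <- 0:(prob$n_terms - 1L)
  M <- pi * (2 * m + 1) / 2
  decay <- exp(-M^2 * Tv)
  vapply(zeta, function(z)
    sum(2 * prob$load / M * sin(M * z) * decay), numeric(1))
}

#' Degree of consolidation of the closed-form solution
#'
#' \eqn{U(T_v) = 1 - \sum_m (2/M^2) e^{-M^2 T_v}}; classical values are
#' U(0.1) = 0.357, U(0.5) = 0.764, U(1.0) = 0.931.
#'
#' @param Tv Dimensionless time factor(s), >= 0.
#' @param n_terms Series truncation order.
#' @return Degree of consolidation in `[0, 1]`.
#' @export
terzaghi_consolidation <- function(Tv, n_terms = 100) {
  m <- 0:(n_terms - 1L)
  M <- pi * (2 * m + 1) / 2
  vapply(Tv, function(s) 1 - sum(2 / M^2 * exp(-M^2 * s)), numeric(1))
}

#' High-accuracy reference for the homogeneous immune kinetics
#'
#' Integrates the spatially uniform limit of the species transport
#' equations with the fluid fraction frozen at `phi`:
#' \deqn{\dot c_p = (\gamma_p - \lambda_{lp} c_l) c_p / \phi, \qquad
#'       \dot c_l = \lambda_{pl} c_p c_l / \phi,}
#' the porosity dividing both rates because the storage term of the
#' transport equations carries the fluid fraction while the reaction
#' sources are per unit total volume. Uses an adaptive integrator at
#' relative tolerance 1e-10, serving as the independent oracle for the
#' solver's ODE limit.
#'
#' @param c_p0,c_l0 Initial concentrations (cell/cm^3), >= 0.
#' @param params A `myo_params` object.
#' @param t_grid Output times (day), starting at 0.
#' @param phi Frozen fluid fraction; defaults to `params$phi0`.
#' @return data.frame with columns `t`, `c_p`, `c_l`.
#' @export
kinetics_reference <- function(c_p0, c_l0, params, t_grid,
                               phi = params$phi0) {
  stopifnot(c_p0 >= 0, c_l0 >= 0, phi > 0)
  deriv <- function(t, y, parms) {
    list(c((parms$gamma_p - parms$lambda_lp * y[2]) * y[1] / phi,
           parms$lambda_pl * y[1] * y[2] / phi))
  }
  out <- deSolve::ode(y = c(c_p = c_p0, c_l = c_l0), times = t_grid,
                      func = deriv, parms = params, method = "lsoda",
                      rtol = 1e-10, atol = 1e-14)
  data.frame(t = out[, "time"], c_p = out[, "c_p"], c_l = out[, "c_l"])
}

#' Capillary-lymphatic balance of the resting tissue
#'
#' Evaluates the fluid exchange at the rest state (p = p0, no pathogen).
#' With the reference parameters the result is a small residual imbalance,
#' below 0.2 percent of the resting lymph flow, which bounds the drift of
#' an uninfected simulation.
#'
#' @param params A `myo_params` object.
#' @return Net volumetric exchange rate (1/day).
#' @export
baseline_balance <- function(params) {
  fluid_exchange(params$p0, 0, params)$total
}

#' Run the verification oracle suite
#'
#' Three checks of the discretisation against independent references:
#' the Terzaghi consolidation benchmark in the linear limit (alpha driven
#' to 1, strains below 1e-3), the uniform-field kinetics limit against the
#' adaptive integrator, and rest-state stability of the uninfected tissue.
#' Problem sizes are kept small; the tolerances are the ones the
#' package's acceptance checks use.
#'
#' @param quiet Suppress per-check messages.
#' @return data.frame with columns `check`, `measure`, `value`,
#'   `tolerance`, `pass`.
#' @export
verify_solver <- function(quiet = FALSE) {
  rows <- list()
  note <- function(...) if (!quiet) message(...)

  # --- Terzaghi -----------------------------------------------------------
  tz <- terzaghi_solver_run()
  err <- max(abs(tz$U_solver - tz$U_exact))
  rows[[1]] <- data.frame(check = "terzaghi",
                          measure = "max |U - U_exact| at Tv=0.1,0.5,1",
                          value = err, tolerance = 0.02, pass = err < 0.02)
  note("Terzaghi: max degree-of-consolidation error ", format(err))

  # --- ODE limit ----------------------------------------------------------
  ode <- kinetics_limit_run()
  rows[[2]] <- data.frame(check = "kinetics-ode-limit",
                          measure = "max rel. error after Richardson",
                          value = ode$rel_err, tolerance = 1e-3,
                          pass = ode$rel_err < 1e-3)
  note("ODE limit: relative error ", format(ode$rel_err))

  # --- rest state ---------------------------------------------------------
  rest <- rest_state_run()
  rows[[3]] <- data.frame(check = "rest-state",
                          measure = "max scaled drift over 150 days",
                          value = rest$drift, tolerance = 1e-3,
                          pass = rest$drift < 1e-3)
  note("Rest state: max scaled drift ", format(rest$drift))

  do.call(rbind, rows)
}

#' Terzaghi benchmark run of the nonlinear solver
#'
#' Configures the solver in its linear consolidation limit (exchange and
#' reactions off, Biot modulus 1, load giving strains of order 1e-3,
#' drained loaded right end) and compares the pressure-based degree of
#' consolidation with the closed-form series at `Tv`.
#'
#' @param Tv Dimensionless times to compare at.
#' @param n_elems Mesh resolution.
#' @param n_steps Number of backward-Euler steps to `Tv = max(Tv)`.
#' @return List with `U_solver`, `U_exact`, `Tv`, and the consolidation
#'   coefficient `c_v` used.
#' @export
terzaghi_solver_run <- function(Tv = c(0.1, 0.5, 1.0), n_elems = 60,
                                n_steps = 400) {
  L <- 1
  load <- 0.07  # mmHg; strain ~ load / (lambda_s + 2 mu_s) ~ 1e-3
  sc <- build_scenario("local-1d", L = L,
                       infected_interval = c(0.4, 0.6), c_p_init = 0,
                       c_l_init = 0,
                       overrides = list(alpha = 1),
                       bc = list(traction_right = -load, p_right = 0),
                       flags = list(exchange = FALSE, reactions = FALSE))
  prm <- sc$params
  M <- prm$lambda_s + 2 * prm$mu_s
  c_v <- prm$kappa0 / prm$mu_f * prm$phi0 * M
  t_end <- max(Tv) * L^2 / c_v
  cfg <- solver_config(dt = t_end / n_steps, t_final = t_end,
                       n_elems = n_elems, snapshot_every = t_end / n_steps)
  traj <- run_simulation(sc, cfg)
  # pressure-based degree of consolidation: U = 1 - int p dX / (load * L)
  snaps <- traj$snapshots
  times <- vapply(snaps, function(s) s$t, numeric(1))
  w <- traj$mesh$w
  U_of <- function(tt) {
    i <- which.min(abs(times - tt))
    1 - sum(w * snaps[[i]]$p) / (load * L)
  }
  t_cmp <- Tv * L^2 / c_v
  list(U_solver = vapply(t_cmp, U_of, numeric(1)),
       U_exact = terzaghi_consolidation(Tv),
       Tv = Tv, c_v = c_v)
}

#' Uniform-field kinetics limit of the solver
#'
#' Runs the solver with spatially uniform initial data, diffusion and
#' chemotaxis off and mechanics frozen, at `dt` and `dt/2`, Richardson
#' extrapolates the backward-Euler error, and compares against
#' [kinetics_reference()] on a grid of output times. Errors are measured
#' relative to each species' trajectory maximum: after the infection
#' resolves the pathogen decays towards zero exponentially, where a
#' pointwise relative error is ill-conditioned.
#'
#' @param kind Scenario preset.
#' @param t_final Horizon (day).
#' @param dt Base step (day).
#' @param t_check Comparison times (day).
#' @return List with `rel_err` (max error over species and times, scaled
#'   by the species' trajectory maximum) and the compared trajectories.
#' @export
kinetics_limit_run <- function(kind = "local-1d", t_final = 150, dt = 0.1,
                               t_check = seq(5, t_final, by = 5)) {
  sc <- build_scenario(kind, infected_interval = c(0, 8),
                       overrides = list(d_p = 0, d_l = 0, chi = 0),
                       flags = list(exchange = FALSE,
                                    freeze_mechanics = TRUE))
  run_at <- function(step) {
    cfg <- solver_config(dt = step, t_final = t_final, n_elems = 4,
                         snapshot_every = t_final)
    traj <- run_simulation(sc, cfg)
    s <- traj$summary
    idx <- vapply(t_check, function(tt) which.min(abs(s$t - tt)),
                  integer(1))
    cbind(c_p = s$mean_c_p[idx], c_l = s$mean_c_l[idx])
  }
  v1 <- run_at(dt)
  v2 <- run_at(dt / 2)
  extrap <- 2 * v2 - v1  # first-order Richardson
  ref <- kinetics_reference(sc$c_p_init, sc$c_l_init, sc$params,
                            c(0, t_check))
  exact <- cbind(c_p = ref$c_p[-1], c_l = ref$c_l[-1])
  scale <- rep(apply(abs(exact), 2, max), each = length(t_check))
  list(rel_err = max(abs(extrap - exact) / scale),
       t_check = t_check, solver = extrap, reference = exact)
}

#' Rest-state stability run
#'
#' Simulates the uninfected tissue (c_p = 0 everywhere) and measures the
#' largest drift of every field from its rest value over the horizon,
#' scaled by a natural magnitude per field (domain length for u, the
#' lymphatic half-saturation pressure for p, phi0 for the fluid phase,
#' and the initial leukocyte concentration).
#'
#' @param t_final Horizon (day).
#' @param n_elems,dt Resolution (spatial detail is irrelevant for the
#'   uniform rest state).
#' @return List with `drift` (max scaled drift) and the per-field drifts.
#' @export
rest_state_run <- function(t_final = 150, n_elems = 40, dt = 0.5) {
  sc <- build_scenario("local-1d", c_p_init = 0)
  cfg <- solver_config(dt = dt, t_final = t_final, n_elems = n_elems,
                       snapshot_every = t_final)
  traj <- run_simulation(sc, cfg)
  s <- traj$summary
  prm <- sc$params
  drifts <- c(
    u = max(abs(s$max_u)) / sc$L,
    p = max(abs(s$max_p)) / prm$k_m,
    phi_f = max(abs(s$max_phi_f - prm$phi0)) / prm$phi0,
    c_p = max(s$max_c_p),
    c_l = max(abs(s$max_c_l - sc$c_l_init)) / sc$c_l_init
  )
  list(drift = max(drifts), per_field = drifts)
}
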