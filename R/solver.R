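# Monolithic implicit solver for the five-field system (u, p, phi_f, c_p,
# c_l) on a 1D interval at finite strain.
#
# Discretisation: continuous piecewise-linear elements for all five fields.
# Storage, reaction and exchange terms use lumped (nodal) quadrature and
# fluxes use midpoint element quadrature; the lumped storage matrix makes
# the backward-Euler transport update an M-matrix, which keeps the species
# concentrations nonnegative even across the sharp initial infection front.
# The saturation constraint J - phi_f = 1 - phi0 is collocated at nodes,
# with the nodal Jacobian J taken as the mean of the two adjacent element
# values. Time integration is backward Euler; each step solves the coupled
# nonlinear system with Newton-Raphson and a colored finite-difference
# sparse Jacobian (3-coloring of the node graph x 5 fields = 15 extra
# residual evaluations per Jacobian).

.FIELDS <- c("u", "p", "phi_f", "c_p", "c_l")

#' Time-stepping and Newton controls
#'
#' @param dt Time step (day). Default 0.1.
#' @param t_final Simulation horizon (day). Default 150.
#' @param newton_tol Convergence tolerance on the 2-norm of the discrete
#'   residual. Default 1e-6.
#' @param newton_max_iter Maximum Newton iterations per step.
#' @param n_elems Number of mesh elements when `run_simulation()` builds
#'   the mesh itself.
#' @param snapshot_every Interval (day) between stored full-field
#'   snapshots; per-step summaries are always stored.
#' @param spread_threshold Pathogen concentration used by the spread-time
#'   summary (cell/cm^3).
#' @param clamp_tol Concentrations in `(-clamp_tol, 0)` after a converged
#'   step are round-off and clamped to zero; more negative values raise an
#'   error.
#' @param fd_eps Relative perturbation of the finite-difference Jacobian.
#' @param max_dt_halvings On Newton failure the step is retried with a
#'   halved dt, recursively, up to this many levels.
#' @return Object of class `myo_solver_config`.
#' @export
solver_config <- function(dt = 0.1, t_final = 150, newton_tol = 1e-6,
                          newton_max_iter = 25, n_elems = 400,
                          snapshot_every = 5, spread_threshold = 1e-4,
                          clamp_tol = 1e-12, fd_eps = 1e-7,
                          max_dt_halvings = 4) {
  stopifnot(dt > 0, t_final > 0, newton_tol > 0, newton_max_iter >= 1,
            n_elems >= 1, snapshot_every > 0)
  structure(list(dt = dt, t_final = t_final, newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 n_elems = as.integer(n_elems),
                 snapshot_every = snapshot_every,
                 spread_threshold = spread_threshold,
                 clamp_tol = clamp_tol, fd_eps = fd_eps,
                 max_dt_halvings = as.integer(max_dt_halvings)),
            class = "myo_solver_config")
}

#' Construct a nodal state
#'
#' @param t Time (day).
#' @param u,p,phi_f,c_p,c_l Nodal field vectors of equal length.
#' @return Object of class `myo_state`.
#' @export
myo_state <- function(t, u, p, phi_f, c_p, c_l) {
  n <- length(u)
  stopifnot(length(p) == n, length(phi_f) == n, length(c_p) == n,
            length(c_l) == n)
  structure(list(t = t, u = u, p = p, phi_f = phi_f, c_p = c_p, c_l = c_l),
            class = "myo_state")
}

.pack_state <- function(s) c(s$u, s$p, s$phi_f, s$c_p, s$c_l)

.unpack_state <- function(y, N, t = NA_real_) {
  myo_state(t, y[1:N], y[N + 1:N], y[2 * N + 1:N], y[3 * N + 1:N],
            y[4 * N + 1:N])
}

# internal: total exchange rate, vectorised, shared with fluid_exchange()
.exchange_total <- function(p, c_p, prm) {
  f <- 1 + prm$c_bp * c_p
  dp <- pmax(p - prm$p0, 0)
  hill <- dp^prm$n_hill / (prm$k_m^prm$n_hill + dp^prm$n_hill)
  hill[dp == 0] <- 0
  prm$S_over_V * prm$L_p0 * f *
    (prm$P_c - p - prm$sigma0 / f * (prm$pi_c - prm$pi_i)) -
    prm$q0 * (1 + prm$v_max * hill)
}

# Build the packed residual closure for one (params, mesh, scenario, dt).
# ynew/yold are packed field-major vectors of length 5N.
.make_residual <- function(params, mesh, scenario, dt) {
  N <- length(mesh$nodes)
  n <- mesh$n_elems
  h <- mesh$h
  w <- mesh$w
  il <- 1:n
  ir <- 2:N
  prm <- params
  mu_s <- prm$mu_s; lambda_s <- prm$lambda_s; alpha <- prm$alpha
  kmob <- prm$kappa0 / prm$mu_f
  d_p <- prm$d_p; d_l <- prm$d_l; chi <- prm$chi
  gamma_p <- prm$gamma_p; lambda_lp <- prm$lambda_lp
  lambda_pl <- prm$lambda_pl
  phi0 <- prm$phi0
  flags <- scenario$flags
  bc <- scenario$bc
  one_m_phi0 <- 1 - phi0

  function(ynew, yold) {
    u <- ynew[1:N]; p <- ynew[N + 1:N]; phi <- ynew[2 * N + 1:N]
    cp <- ynew[3 * N + 1:N]; cl <- ynew[4 * N + 1:N]
    if (anyNA(ynew) || any(!is.finite(ynew))) {
      bad <- .FIELDS[unique((which(!is.finite(ynew)) - 1) %/% N) + 1]
      stop("numerical failure: non-finite values in field(s) ",
           paste(bad, collapse = ", "))
    }
    phio <- yold[2 * N + 1:N]
    cpo <- yold[3 * N + 1:N]; clo <- yold[4 * N + 1:N]

    F <- 1 + (u[ir] - u[il]) / h
    if (any(F <= 0))
      stop("kinematic violation: element Jacobian J <= 0")
    pm <- 0.5 * (p[il] + p[ir])
    phim <- 0.5 * (phi[il] + phi[ir])
    clm <- 0.5 * (cl[il] + cl[ir])
    Jn <- c(F[1], 0.5 * (F[-1] + F[-n]), F[n])
    if (n == 1L) Jn <- c(F, F)

    # momentum: total 1D Piola stress per element
    Peff <- mu_s * (F - 1 / F) + lambda_s * log(F) / F
    S <- Peff - alpha * pm
    Ru <- numeric(N)
    Ru[il] <- Ru[il] - S
    Ru[ir] <- Ru[ir] + S
    Ru[N] <- Ru[N] - bc$traction_right
    Ru[1] <- u[1] - bc$u_left   # essential condition, strong row

    # fluid mass balance
    ell <- if (flags$exchange) .exchange_total(p, cp, prm) else 0
    qp <- phim * kmob * (p[ir] - p[il]) / (h * F)
    Rp <- w * Jn * ((phi - phio) / dt - ell)
    Rp[il] <- Rp[il] - qp
    Rp[ir] <- Rp[ir] + qp
    if (!is.na(bc$p_left)) Rp[1] <- p[1] - bc$p_left
    if (!is.na(bc$p_right)) Rp[N] <- p[N] - bc$p_right

    # saturation constraint, collocated at nodes
    Rphi <- Jn - phi - one_m_phi0

    # species transport; reactions are per-fluid-volume sources
    if (flags$reactions) {
      rp <- (gamma_p - lambda_lp * cl) * cp
      rl <- lambda_pl * cp * cl
    } else {
      rp <- 0; rl <- 0
    }
    qcp <- phim * d_p * (cp[ir] - cp[il]) / (h * F)
    Rcp <- w * Jn * ((phi * cp - phio * cpo) / dt - rp)
    Rcp[il] <- Rcp[il] - qcp
    Rcp[ir] <- Rcp[ir] + qcp

    qcl <- phim * d_l * (cl[ir] - cl[il]) / (h * F) -
      chi * phim * clm * (cp[ir] - cp[il]) / (h * F)
    Rcl <- w * Jn * ((phi * cl - phio * clo) / dt - rl)
    Rcl[il] <- Rcl[il] - qcl
    Rcl[ir] <- Rcl[ir] + qcl

    if (flags$freeze_mechanics) {
      Ru <- u
      Rp <- p
      Rphi <- phi - phi0
    }
    c(Ru, Rp, Rphi, Rcp, Rcl)
  }
}

# Colored finite-difference Jacobian infrastructure: node colors (i-1) %% 3
# guarantee columns in one group touch disjoint row neighbourhoods.
.make_fd_jacobian <- function(N, fd_eps) {
  colors <- (seq_len(N) - 1L) %% 3L
  # mm_map[m, c+1]: the unique node in {m-1, m, m+1} with color c, or NA
  mm_map <- matrix(NA_integer_, N, 3)
  for (c in 0:2) {
    for (d in -1:1) {
      cand <- seq_len(N) + d
      ok <- cand >= 1L & cand <= N
      hit <- ok & ((cand - 1L) %% 3L == c)
      mm_map[hit, c + 1] <- cand[hit]
    }
  }
  groups <- vector("list", 15L)
  ii <- jj <- vector("list", 15L)
  g <- 0L
  for (f in 1:5) {
    for (c in 0:2) {
      g <- g + 1L
      sel <- which(colors == c) + (f - 1L) * N
      mm <- mm_map[, c + 1]
      ok <- which(!is.na(mm))
      rows <- as.vector(outer(ok, (0:4) * N, `+`))
      cols <- rep((f - 1L) * N + mm[ok], 5L)
      groups[[g]] <- list(f = f, sel = sel, rows = rows, cols = cols)
      ii[[g]] <- rows
      jj[[g]] <- cols
    }
  }
  typ <- c(1e-2, 1e-1, 1e-1, 1e-3, 1e-3)  # u, p, phi, cp, cl scales
  list(
    pattern_i = unlist(ii), pattern_j = unlist(jj),
    fill = function(resid_fn, y, yold, r0) {
      xs <- vector("list", 15L)
      epsfull <- numeric(5L * N)
      for (g in seq_along(groups)) {
        gr <- groups[[g]]
        epsv <- numeric(5L * N)
        eps <- fd_eps * pmax(abs(y[gr$sel]), typ[gr$f])
        epsv[gr$sel] <- eps
        dr <- resid_fn(y + epsv, yold) - r0
        epsfull[gr$sel] <- eps
        xs[[g]] <- dr[gr$rows] / epsfull[gr$cols]
      }
      unlist(xs)
    }
  )
}

#' Assemble the discrete residual of the five-field system
#'
#' Backward-Euler weak-form residual of the momentum balance, fluid mass
#' balance, saturation constraint and the two species transport equations,
#' evaluated at `state_new` given the previous step `state_old`.
#' Primarily a building block of [newton_step()] and of verification
#' tests; the rest state with the exchange term disabled is an exact root.
#'
#' @param state_new,state_old `myo_state` objects on the same mesh.
#' @param dt Time step (day).
#' @param params A `myo_params` object.
#' @param mesh A `myo_mesh` object.
#' @param scenario A `myo_scenario` object (boundary conditions and term
#'   flags); defaults to the plain no-flux/traction-free configuration.
#' @return Numeric residual vector of length `5 * n_nodes`, ordered
#'   field-major (u, p, phi_f, c_p, c_l).
#' @export
assemble_residual <- function(state_new, state_old, dt, params, mesh,
                              scenario = NULL) {
  if (is.null(scenario))
    scenario <- build_scenario("local-1d", L = mesh$L)
  rf <- .make_residual(params, mesh, scenario, dt)
  rf(.pack_state(state_new), .pack_state(state_old))
}

#' One backward-Euler step by Newton-Raphson
#'
#' Solves the monolithic nonlinear system for the state at `t + dt`,
#' starting from `state_guess`. The Jacobian is a colored
#' finite-difference approximation with the exact sparsity pattern of the
#' 1D discretisation. Updates that produce non-finite residuals or
#' inverted elements are backtracked by halving.
#'
#' @param state_guess Initial Newton iterate (usually the old state).
#' @param state_old Converged state at the previous time level.
#' @param dt Time step (day).
#' @param params,mesh,scenario Model definition (see [assemble_residual()]).
#' @param config A `myo_solver_config`.
#' @return The converged `myo_state` at `state_old$t + dt`.
#' @export
newton_step <- function(state_guess, state_old, dt, params, mesh, scenario,
                        config = solver_config()) {
  N <- length(mesh$nodes)
  rf <- .make_residual(params, mesh, scenario, dt)
  fd <- .make_fd_jacobian(N, config$fd_eps)
  yold <- .pack_state(state_old)
  y <- .newton_solve(.pack_state(state_guess), yold, rf, fd, N, config)
  .unpack_state(y, N, t = state_old$t + dt)
}

# core Newton loop on packed vectors; returns y or stops
.newton_solve <- function(y, yold, rf, fd, N, config) {
  r <- rf(y, yold)
  rnorm <- sqrt(sum(r * r))
  for (k in seq_len(config$newton_max_iter)) {
    if (rnorm <= config$newton_tol) {
      attr(y, "iters") <- k - 1L
      return(y)
    }
    x <- fd$fill(rf, y, yold, r)
    J <- Matrix::sparseMatrix(i = fd$pattern_i, j = fd$pattern_j, x = x,
                              dims = c(5L * N, 5L * N))
    dy <- tryCatch(as.numeric(Matrix::solve(J, r)),
                   error = function(e) stop("singular Jacobian: ",
                                            conditionMessage(e)))
    step <- 1
    repeat {
      ytry <- y - step * dy
      rtry <- tryCatch(rf(ytry, yold), error = function(e) NULL)
      if (!is.null(rtry) && all(is.finite(rtry))) break
      step <- step / 2
      if (step < 1 / 64)
        stop("Newton backtracking failed (residual norm ",
             format(rnorm), ")")
    }
    y <- ytry
    r <- rtry
    rnorm <- sqrt(sum(r * r))
  }
  if (rnorm <= config$newton_tol) {
    attr(y, "iters") <- config$newton_max_iter
    return(y)
  }
  stop("Newton did not converge in ", config$newton_max_iter,
       " iterations; last residual norm ", format(rnorm))
}

# advance one step of size dt with recursive halving on failure
.advance <- function(y, t, dt, rf_cache, fd, N, config, depth = 0L) {
  rf <- rf_cache(dt)
  ok <- tryCatch(
    list(y = .newton_solve(y, y, rf, fd, N, config)),
    error = function(e) e
  )
  if (!inherits(ok, "error")) return(ok$y)
  if (depth >= config$max_dt_halvings)
    stop("time step failed at t = ", format(t), " day: ",
         conditionMessage(ok))
  y1 <- .advance(y, t, dt / 2, rf_cache, fd, N, config, depth + 1L)
  .advance(y1, t + dt / 2, dt / 2, rf_cache, fd, N, config, depth + 1L)
}

#' Run a full simulation
#'
#' Advances the coupled system by backward Euler from t = 0 to
#' `config$t_final`, storing per-step spatial summaries and periodic
#' full-field snapshots. The model is deterministic: identical inputs give
#' bit-identical trajectories.
#'
#' @param scenario A `myo_scenario` from [build_scenario()].
#' @param config A `myo_solver_config`.
#' @param mesh Optional `myo_mesh`; defaults to a uniform mesh with
#'   `config$n_elems` elements on `[0, scenario$L]`.
#' @return Object of class `myo_trajectory`: list with `summary` (one row
#'   per step: time, spatial means, maxima, boundary pathogen values,
#'   Newton iteration count), `snapshots` (list of `myo_state`), `mesh`,
#'   `scenario`, `params`, `config`.
#' @examples
#' \donttest{
#' sc <- build_scenario("local-1d")
#' traj <- run_simulation(sc, solver_config(t_final = 2, n_elems = 50))
#' tail(traj$summary)
#' }
#' @export
run_simulation <- function(scenario, config = solver_config(), mesh = NULL) {
  stopifnot(inherits(scenario, "myo_scenario"),
            inherits(config, "myo_solver_config"))
  if (is.null(mesh)) mesh <- mesh_1d(scenario$L, config$n_elems)
  params <- scenario$params
  N <- length(mesh$nodes)
  state0 <- initial_state(scenario, mesh)
  fd <- .make_fd_jacobian(N, config$fd_eps)

  # residual closures per dt are cached (dt halving reuses them)
  rf_memo <- new.env(parent = emptyenv())
  rf_cache <- function(dt) {
    key <- format(dt, digits = 17)
    if (is.null(rf_memo[[key]]))
      rf_memo[[key]] <- .make_residual(params, mesh, scenario, dt)
    rf_memo[[key]]
  }

  nt <- ceiling(config$t_final / config$dt - 1e-9)
  times <- seq_len(nt) * config$dt
  times[nt] <- config$t_final

  wL <- mesh$w / mesh$L
  summarise_row <- function(s, iters) {
    c(t = s$t,
      mean_u = sum(wL * s$u), mean_p = sum(wL * s$p),
      mean_phi_f = sum(wL * s$phi_f), mean_c_p = sum(wL * s$c_p),
      mean_c_l = sum(wL * s$c_l),
      max_u = max(s$u), max_p = max(s$p), max_phi_f = max(s$phi_f),
      max_c_p = max(s$c_p), max_c_l = max(s$c_l),
      c_p_left = s$c_p[1], c_p_right = s$c_p[N],
      newton_iters = iters)
  }

  rows <- vector("list", nt + 1L)
  rows[[1]] <- summarise_row(state0, 0L)
  snapshots <- list(state0)
  next_snap <- config$snapshot_every

  y <- .pack_state(state0)
  t_prev <- 0
  for (k in seq_len(nt)) {
    dt_k <- times[k] - t_prev
    y <- tryCatch(
      .advance(y, t_prev, dt_k, rf_cache, fd, N, config),
      error = function(e) stop("simulation failed at t = ",
                               format(times[k]), " day: ",
                               conditionMessage(e))
    )
    iters <- attr(y, "iters")
    # clamp round-off negatives in the concentrations
    conc <- y[3 * N + 1:(2 * N)]
    neg <- conc < 0
    if (any(neg)) {
      worst <- min(conc[neg])
      if (worst < -config$clamp_tol)
        stop("negative concentration ", format(worst), " at t = ",
             format(times[k]), " day exceeds the round-off clamp")
      conc[neg] <- 0
      y[3 * N + 1:(2 * N)] <- conc
    }
    t_prev <- times[k]
    s <- .unpack_state(y, N, t = times[k])
    rows[[k + 1L]] <- summarise_row(s, if (is.null(iters)) NA_integer_ else iters)
    if (times[k] + 1e-9 >= next_snap || k == nt) {
      snapshots[[length(snapshots) + 1L]] <- s
      next_snap <- next_snap + config$snapshot_every
    }
  }

  summary <- as.data.frame(do.call(rbind, rows))
  structure(list(summary = summary, snapshots = snapshots, mesh = mesh,
                 scenario = scenario, params = params, config = config),
            class = "myo_trajectory")
}
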