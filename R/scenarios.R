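# Reference 1D scenarios and the one-at-a-time sensitivity driver.

#' Build a reference 1D myocarditis scenario
#'
#' The reference strip is the interval `[0, 8]` cm with the infection
#' seeded in `[3.8, 4.2]` cm: pathogen concentration 0.001 cell/cm^3
#' inside, 0 outside; leukocytes 0.003 cell/cm^3 everywhere; fluid phase
#' at its resting fraction phi0 = 0.2; zero displacement and pressure.
#' Boundary conditions: u = 0 at x = 0, traction-free at x = L, zero-flux
#' for p, c_p, c_l at both ends.
#'
#' @param kind `"local-1d"` or `"diffuse-1d"` (the two 1D presets; the 3D
#'   parameter columns are available through [reference_parameters()] but
#'   have no 1D scenario).
#' @param L Domain length (cm).
#' @param infected_interval Numeric `c(lo, hi)` delimiting the initially
#'   infected region.
#' @param c_p_init,c_l_init Initial concentrations (cell/cm^3).
#' @param overrides Named list of parameter overrides applied with
#'   [set_parameter()] (e.g. `list(gamma_p = 0.18)`).
#' @param bc Named list overriding boundary conditions: `u_left` (essential
#'   displacement), `traction_right` (applied 1st Piola traction, mmHg),
#'   `p_left`/`p_right` (Dirichlet pressure, `NA` = natural zero-flux).
#' @param flags Named list of term switches: `exchange`, `reactions`
#'   (logical), `freeze_mechanics` (replace the mechanical rows by the rest
#'   state; used by the kinetics verification limit).
#' @return Object of class `myo_scenario`.
#' @examples
#' sc <- build_scenario("local-1d")
#' sc$infected_interval
#' @export
build_scenario <- function(kind = c("local-1d", "diffuse-1d"), L = 8,
                           infected_interval = c(3.8, 4.2),
                           c_p_init = 0.001, c_l_init = 0.003,
                           overrides = list(), bc = list(), flags = list()) {
  kind <- match.arg(kind)
  stopifnot(L > 0, length(infected_interval) == 2,
            infected_interval[1] >= 0, infected_interval[2] <= L,
            infected_interval[1] < infected_interval[2],
            c_p_init >= 0, c_l_init >= 0)
  params <- reference_parameters(kind)
  for (nm in names(overrides))
    params <- set_parameter(params, nm, overrides[[nm]])
  bc_full <- list(u_left = 0, traction_right = 0,
                  p_left = NA_real_, p_right = NA_real_)
  unknown <- setdiff(names(bc), names(bc_full))
  if (length(unknown))
    stop("unknown boundary condition(s): ", paste(unknown, collapse = ", "))
  bc_full[names(bc)] <- bc
  flags_full <- list(exchange = TRUE, reactions = TRUE,
                     freeze_mechanics = FALSE)
  unknown <- setdiff(names(flags), names(flags_full))
  if (length(unknown))
    stop("unknown flag(s): ", paste(unknown, collapse = ", "))
  flags_full[names(flags)] <- flags
  structure(list(preset = kind, L = L,
                 infected_interval = infected_interval,
                 c_p_init = c_p_init, c_l_init = c_l_init,
                 phi0 = params$phi0, params = params,
                 overrides = overrides, bc = bc_full, flags = flags_full),
            class = "myo_scenario")
}

#' @export
print.myo_scenario <- function(x, ...) {
  cat("Myocarditis scenario '", x$preset, "' on [0, ", format(x$L),
      "] cm\n", sep = "")
  cat("  infected region: [", x$infected_interval[1], ", ",
      x$infected_interval[2], "] cm, c_p = ", x$c_p_init,
      ", c_l = ", x$c_l_init, " cell/cm^3\n", sep = "")
  if (length(x$overrides))
    cat("  overrides:", paste(names(x$overrides), unlist(x$overrides),
                              sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Initial nodal state for a scenario
#'
#' @param scenario A `myo_scenario`.
#' @param mesh A `myo_mesh`.
#' @return A `myo_state` at t = 0: u = 0, p = 0, phi_f = phi0, c_p seeded
#'   on the infected interval (node-inclusive), c_l uniform.
#' @export
initial_state <- function(scenario, mesh) {
  x <- mesh$nodes
  tol <- 1e-9
  inside <- x >= scenario$infected_interval[1] - tol &
    x <= scenario$infected_interval[2] + tol
  myo_state(0,
            u = numeric(length(x)),
            p = numeric(length(x)),
            phi_f = rep(scenario$phi0, length(x)),
            c_p = ifelse(inside, scenario$c_p_init, 0),
            c_l = rep(scenario$c_l_init, length(x)))
}

#' One-at-a-time parameter sensitivity
#'
#' Re-runs a scenario with a single parameter scaled by each factor
#' (reference protocol: halved, reference, doubled), all other parameters
#' held at their reference values. Scaling `E` re-derives the Lame
#' parameters.
#'
#' @param base A `myo_scenario` (the unscaled reference).
#' @param parameter Name of the parameter to scale (a `myo_params` field).
#' @param factors Numeric scale factors, default `c(0.5, 1, 2)`.
#' @param config A `myo_solver_config`.
#' @return List of class `myo_oat` with one element per factor:
#'   `list(factor, value, summary, peaks)` where `summary` is the
#'   trajectory's per-step table and `peaks` the [summarize()] record.
#' @export
oat_sensitivity <- function(base, parameter, factors = c(0.5, 1, 2),
                            config = solver_config()) {
  stopifnot(inherits(base, "myo_scenario"))
  if (!parameter %in% names(base$params))
    stop("unknown parameter '", parameter, "'")
  if (!length(factors)) stop("factors must be a nonempty numeric vector")
  ref_val <- base$params[[parameter]]
  out <- lapply(factors, function(f) {
    sc <- base
    sc$params <- set_parameter(sc$params, parameter, f * ref_val)
    sc$overrides[[parameter]] <- f * ref_val
    traj <- run_simulation(sc, config)
    list(factor = f, value = f * ref_val, summary = traj$summary,
         peaks = summarize(traj))
  })
  structure(out, class = "myo_oat", parameter = parameter,
            preset = base$preset)
}

#' Long-format time series for the sensitivity figure panels
#'
#' For one of the four analysed parameters (Young's modulus `E`, pathogen
#' reproduction rate `gamma_p`, phagocytosis rate `lambda_lp`, pathogen
#' diffusivity `d_p`), returns the spatial-mean evolution of all five
#' fields over the simulation horizon for each scale factor, in long
#' format (factor, t, field, value) ready for plotting.
#'
#' @param parameter One of `"E"`, `"gamma_p"`, `"lambda_lp"`, `"d_p"`.
#' @param kind Scenario preset (`"local-1d"` or `"diffuse-1d"`).
#' @param factors Scale factors, nonempty; default `c(0.5, 1, 2)`.
#' @param config A `myo_solver_config`.
#' @return A long-format `data.frame` with columns `factor`, `t`, `field`,
#'   `value`.
#' @export
fig_sensitivity_panel <- function(parameter, kind = "local-1d",
                                  factors = c(0.5, 1, 2),
                                  config = solver_config()) {
  allowed <- c("E", "gamma_p", "lambda_lp", "d_p")
  if (!parameter %in% allowed)
    stop("panel reproduction supports ", paste(allowed, collapse = ", "),
         "; other parameters remain available via oat_sensitivity()")
  if (!length(factors)) stop("factors must be a nonempty numeric vector")
  oat <- oat_sensitivity(build_scenario(kind), parameter, factors, config)
  fields <- c("mean_u", "mean_p", "mean_phi_f", "mean_c_p", "mean_c_l")
  do.call(rbind, lapply(oat, function(run) {
    do.call(rbind, lapply(fields, function(f)
      data.frame(factor = run$factor, t = run$summary$t,
                 field = sub("^mean_", "", f), value = run$summary[[f]])))
  }))
}
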