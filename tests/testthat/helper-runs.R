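# Shared fixtures: memoised simulation runs so expensive trajectories are
# computed once per test session.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, scenario, config) {
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_simulation(scenario, config)
  .run_cache[[key]]
}

# coarse configuration used by structural/property tests: resolves the
# infected region (h = 0.08 cm) and the reaction fronts while keeping a
# 150-day run to a few seconds
coarse_config <- function(t_final = 150, dt = 0.25, n_elems = 100, ...) {
  solver_config(dt = dt, t_final = t_final, n_elems = n_elems, ...)
}

# full-resolution configuration of the reference dynamics runs
reference_config <- function(t_final = 150) {
  solver_config(dt = 0.1, t_final = 150, n_elems = 400)
}

local_run_full <- function() {
  cached_run("local-full", build_scenario("local-1d"), reference_config())
}

diffuse_run_full <- function() {
  cached_run("diffuse-full", build_scenario("diffuse-1d"),
             reference_config())
}
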