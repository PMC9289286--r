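# Configuration parsing, result serialisation and the command-line
# entry point.

.config_keys <- c("preset", "L", "infected_lo", "infected_hi",
                  "c_p_init", "c_l_init",
                  "dt", "t_final", "newton_tol", "newton_max_iter",
                  "n_elems", "snapshot_every", "spread_threshold")

#' Load scenario and solver configuration from a plain-text file
#'
#' The file holds `key: value` lines (or `key = value`; `#` starts a
#' comment). Recognised keys: `preset` (required), `L`, `infected_lo`,
#' `infected_hi`, `c_p_init`, `c_l_init`, and the solver controls `dt`,
#' `t_final`, `newton_tol`, `newton_max_iter`, `n_elems`,
#' `snapshot_every`, `spread_threshold`. Parameter overrides use a
#' `param.` prefix, e.g. `param.gamma_p: 0.18`. Unknown keys are
#' rejected by name.
#'
#' @param path Config file path.
#' @return List with elements `scenario` (a `myo_scenario`) and `config`
#'   (a `myo_solver_config`).
#' @export
load_config <- function(path) {
  kv <- .read_keyvalue(path)
  if (is.null(kv$preset)) stop("config must name a 'preset'")
  overrides <- list()
  plain <- list()
  for (nm in names(kv)) {
    if (startsWith(nm, "param.")) {
      overrides[[sub("^param\\.", "", nm)]] <- as.numeric(kv[[nm]])
    } else if (nm %in% .config_keys) {
      plain[[nm]] <- kv[[nm]]
    } else {
      stop("unknown configuration key '", nm, "'")
    }
  }
  num <- function(key, default) {
    if (is.null(plain[[key]])) default else as.numeric(plain[[key]])
  }
  scenario <- build_scenario(
    kind = plain$preset,
    L = num("L", 8),
    infected_interval = c(num("infected_lo", 3.8), num("infected_hi", 4.2)),
    c_p_init = num("c_p_init", 0.001),
    c_l_init = num("c_l_init", 0.003),
    overrides = overrides
  )
  config <- solver_config(
    dt = num("dt", 0.1), t_final = num("t_final", 150),
    newton_tol = num("newton_tol", 1e-6),
    newton_max_iter = num("newton_max_iter", 25),
    n_elems = num("n_elems", 400),
    snapshot_every = num("snapshot_every", 5),
    spread_threshold = num("spread_threshold", 1e-4)
  )
  list(scenario = scenario, config = config)
}

#' Write one snapshot as a columnar text file
#'
#' Columns: x, u, p, phi_f, c_p, c_l (space-separated, header line).
#'
#' @param state A `myo_state`.
#' @param mesh The `myo_mesh` the state lives on.
#' @param path Output path.
#' @export
write_snapshot <- function(state, mesh, path) {
  df <- data.frame(x = mesh$nodes, u = state$u, p = state$p,
                   phi_f = state$phi_f, c_p = state$c_p, c_l = state$c_l)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a full run: manifest, summary table and snapshots
#'
#' Writes `manifest.txt` (scenario, resolved parameters and solver
#' controls: enough to reproduce the run bit-identically),
#' `summary.csv` (per-step spatial means/maxima) and one
#' `snapshot_t<T>.txt` per stored snapshot into `dir`.
#'
#' @param traj A `myo_trajectory`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
save_run <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- traj$scenario
  cfg <- traj$config
  man <- c(
    sprintf("preset: %s", sc$preset),
    sprintf("L: %.17g", sc$L),
    sprintf("infected_lo: %.17g", sc$infected_interval[1]),
    sprintf("infected_hi: %.17g", sc$infected_interval[2]),
    sprintf("c_p_init: %.17g", sc$c_p_init),
    sprintf("c_l_init: %.17g", sc$c_l_init),
    sprintf("dt: %.17g", cfg$dt),
    sprintf("t_final: %.17g", cfg$t_final),
    sprintf("newton_tol: %.17g", cfg$newton_tol),
    sprintf("newton_max_iter: %d", cfg$newton_max_iter),
    sprintf("n_elems: %d", cfg$n_elems),
    sprintf("snapshot_every: %.17g", cfg$snapshot_every),
    sprintf("spread_threshold: %.17g", cfg$spread_threshold),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("poroedema"))),
    sprintf("written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    vapply(names(sc$overrides), function(nm)
      sprintf("param.%s: %.17g", nm, sc$overrides[[nm]]), character(1))
  )
  writeLines(man, file.path(dir, "manifest.txt"))
  utils::write.csv(traj$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  for (s in traj$snapshots)
    write_snapshot(s, traj$mesh,
                   file.path(dir, sprintf("snapshot_t%g.txt", s$t)))
  invisible(dir)
}

#' Re-run a simulation from a saved manifest
#'
#' @param path Path to a `manifest.txt` written by [save_run()].
#' @return A `myo_trajectory`.
#' @export
run_from_manifest <- function(path) {
  kv <- .read_keyvalue(path)
  kv$package_version <- NULL
  kv$written <- NULL
  tmp <- tempfile(fileext = ".cfg")
  on.exit(unlink(tmp))
  writeLines(vapply(names(kv), function(nm)
    paste0(nm, ": ", kv[[nm]]), character(1)), tmp)
  lc <- load_config(tmp)
  run_simulation(lc$scenario, lc$config)
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{run}{`run --preset local-1d [--config FILE] [--t-final N]
#'     [--dt N] [--n-elems N] [--out DIR]` -- simulate one scenario and
#'     save manifest, summary and snapshots.}
#'   \item{sensitivity}{`sensitivity --preset local-1d --parameter gamma_p
#'     [--factors 0.5,1,2] [--out DIR]` -- one-at-a-time driver; writes a
#'     long-format CSV per parameter.}
#'   \item{verify}{runs the oracle suite and prints a pass/fail table.}
#' }
#'
#' @param argv Character vector of arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code: 0 success, 1 failure, 2 usage error.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: poroedema <run|sensitivity|verify> [options]\n",
        "  run         --preset local-1d|diffuse-1d [--config FILE]\n",
        "              [--t-final N] [--dt N] [--n-elems N] [--out DIR]\n",
        "  sensitivity --preset P --parameter NAME [--factors 0.5,1,2]\n",
        "              [--t-final N] [--dt N] [--n-elems N] [--out DIR]\n",
        "  verify\n", sep = "")
    2L
  }
  if (!length(argv)) return(usage())
  cmd <- argv[1]
  opts <- .parse_cli_options(argv[-1])
  if (inherits(opts, "error")) {
    cat("error:", conditionMessage(opts), "\n")
    return(usage())
  }
  res <- tryCatch({
    switch(cmd,
      run = {
        lc <- .cli_configs(opts)
        traj <- run_simulation(lc$scenario, lc$config)
        out <- if (is.null(opts$out)) "poroedema-run" else opts$out
        save_run(traj, out)
        pk <- summarize(traj)
        print(pk)
        cat("results written to ", out, "\n", sep = "")
        0L
      },
      sensitivity = {
        if (is.null(opts$parameter)) stop("--parameter is required")
        lc <- .cli_configs(opts)
        factors <- if (is.null(opts$factors)) c(0.5, 1, 2) else
          as.numeric(strsplit(opts$factors, ",")[[1]])
        panel <- fig_sensitivity_panel(opts$parameter,
                                       kind = lc$scenario$preset,
                                       factors = factors,
                                       config = lc$config)
        out <- if (is.null(opts$out)) "poroedema-sensitivity" else opts$out
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        f <- file.path(out, sprintf("%s_%s.csv", lc$scenario$preset,
                                    opts$parameter))
        utils::write.csv(panel, f, row.names = FALSE)
        cat("panel written to ", f, "\n", sep = "")
        0L
      },
      {
        if (cmd != "verify") return(usage())
        tab <- verify_solver(quiet = TRUE)
        print(tab, row.names = FALSE)
        if (all(tab$pass)) 0L else 1L
      }
    )
  }, error = function(e) {
    cat("error:", conditionMessage(e), "\n")
    1L
  })
  res
}

.parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      return(simpleError(paste0("unexpected argument '", a, "'")))
    key <- gsub("-", "_", sub("^--", "", a))
    if (i == length(args))
      return(simpleError(paste0("missing value for ", a)))
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.cli_configs <- function(opts) {
  if (!is.null(opts$config)) {
    lc <- load_config(opts$config)
  } else {
    if (is.null(opts$preset)) stop("--preset (or --config) is required")
    lc <- list(scenario = build_scenario(opts$preset),
               config = solver_config())
  }
  cfg <- lc$config
  if (!is.null(opts$t_final)) cfg$t_final <- as.numeric(opts$t_final)
  if (!is.null(opts$dt)) cfg$dt <- as.numeric(opts$dt)
  if (!is.null(opts$n_elems)) cfg$n_elems <- as.integer(opts$n_elems)
  lc$config <- cfg
  lc
}
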