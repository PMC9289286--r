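# Trajectory summaries and S3 methods.

#' Summarise a simulated trajectory
#'
#' Computes, from the per-step spatial summaries, the peak (global-in-time
#' maximum of the spatial maximum) of every field with its time, and the
#' spread time: the first instant at which the pathogen concentration
#' exceeds a threshold at both boundary nodes.
#'
#' @param traj A `myo_trajectory` from [run_simulation()].
#' @param spread_threshold Pathogen threshold (cell/cm^3); defaults to the
#'   value in the trajectory's solver config.
#' @return Object of class `myo_summary`: list with `peaks` (data.frame:
#'   field, peak_time, peak_value), `spread_time` (NA if the pathogen
#'   never reaches both boundaries) and `threshold`.
#' @export
summarize <- function(traj, spread_threshold = NULL) {
  stopifnot(inherits(traj, "myo_trajectory"))
  if (nrow(traj$summary) == 0) stop("empty trajectory")
  if (is.null(spread_threshold))
    spread_threshold <- traj$config$spread_threshold
  s <- traj$summary
  fields <- c("u", "p", "phi_f", "c_p", "c_l")
  peaks <- do.call(rbind, lapply(fields, function(f) {
    v <- s[[paste0("max_", f)]]
    i <- which.max(v)
    # a flat trajectory has no meaningful peak
    flat <- diff(range(v)) <= .Machine$double.eps * max(abs(v), 1)
    data.frame(field = f,
               peak_time = if (flat) NA_real_ else s$t[i],
               peak_value = v[i])
  }))
  hit <- s$c_p_left > spread_threshold & s$c_p_right > spread_threshold
  spread_time <- if (any(hit)) s$t[which(hit)[1]] else NA_real_
  structure(list(peaks = peaks, spread_time = spread_time,
                 threshold = spread_threshold),
            class = "myo_summary")
}

#' @export
print.myo_summary <- function(x, ...) {
  cat("Trajectory summary\n")
  print(x$peaks, row.names = FALSE)
  if (is.na(x$spread_time)) {
    cat("pathogen never exceeds", format(x$threshold),
        "at both boundaries\n")
  } else {
    cat("pathogen exceeds", format(x$threshold),
        "at both boundaries from t =", format(x$spread_time), "day\n")
  }
  invisible(x)
}

#' @export
print.myo_trajectory <- function(x, ...) {
  s <- x$summary
  cat("Myocarditis simulation ('", x$scenario$preset, "'): ",
      nrow(s) - 1L, " steps to t = ", format(max(s$t)), " day, ",
      length(x$snapshots), " snapshots, ", length(x$mesh$nodes),
      " nodes\n", sep = "")
  pk <- summarize(x)
  i <- match("c_p", pk$peaks$field)
  if (!is.na(pk$peaks$peak_time[i]))
    cat("pathogen peak ", format(pk$peaks$peak_value[i], digits = 4),
        " cell/cm^3 at t = ", format(pk$peaks$peak_time[i]), " day\n",
        sep = "")
  invisible(x)
}

#' @export
summary.myo_trajectory <- function(object, ...) summarize(object)

#' Plot the spatial-mean evolution of a simulated trajectory
#'
#' One panel per field (displacement, pressure, fluid phase, pathogen,
#' leukocytes), spatial mean against time. Base graphics.
#'
#' @param x A `myo_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.myo_trajectory <- function(x, ...) {
  s <- x$summary
  fields <- c(mean_u = "displacement [cm]", mean_p = "pressure [mmHg]",
              mean_phi_f = "fluid phase [-]",
              mean_c_p = "pathogen [cell/cm3]",
              mean_c_l = "leukocytes [cell/cm3]")
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (f in names(fields)) {
    graphics::plot(s$t, s[[f]], type = "l", xlab = "t [day]",
                   ylab = fields[[f]], ...)
  }
  invisible(x)
}
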