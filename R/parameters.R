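# Model constants, unit normalisation and reference presets.
#
# Internal unit system: {cm, day, mmHg, cell/cm^3}. Days match the
# reaction/diffusion rates and the simulated horizon (20-150 days);
# mmHg matches every pressure entering the capillary exchange term.

.day_per_s <- 86400
.mmHg_per_kg_cm_s2 <- 1 / 1.33322  # 1 mmHg = 1.33322 kg/(cm s^2)

# units understood by normalize_units(); value = factor into internal units
.unit_table <- list(
  # already internal
  "mmHg"            = 1,
  "1/day"           = 1,
  "day"             = 1,
  "cm"              = 1,
  "1/cm"            = 1,
  "cm2/day"         = 1,
  "cm/(day*mmHg)"   = 1,
  "cm2/(day*mmHg)"  = 1,
  "1/(day*cell/cm3)" = 1,
  "cm2/(day*cell/cm3)" = 1,
  "1/(cell/cm3)"    = 1,
  "cell/cm3"        = 1,
  "kg/cm3"          = 1,
  "-"               = 1,
  # printed source units needing conversion
  "1/s"             = .day_per_s,
  "cm2/s"           = .day_per_s,
  "cm/(s*mmHg)"     = .day_per_s,
  "cm2/(s*mmHg)"    = .day_per_s,
  "kg/(cm*s2)"      = .mmHg_per_kg_cm_s2
)

#' Lame parameters from Young's modulus and Poisson's ratio
#'
#' For the isotropic neo-Hookean skeleton the two Lame constants are
#' \eqn{\mu_s = E / (2(1+\nu))} and
#' \eqn{\lambda_s = E\nu / ((1+\nu)(1-2\nu))}.
#'
#' @param E Young's modulus (any pressure unit; output shares it). Must be > 0.
#' @param nu Poisson's ratio, in `[0, 0.5)`.
#' @return Named numeric vector with components `mu_s` and `lambda_s`.
#' @examples
#' lame_from_elastic(60, 0.35)
#' @export
lame_from_elastic <- function(E, nu) {
  stopifnot(is.numeric(E), is.numeric(nu), length(E) == 1L, length(nu) == 1L)
  if (!is.finite(E) || E <= 0)
    stop("Young's modulus E must be positive, got ", E)
  if (!is.finite(nu) || nu < 0 || nu >= 0.5)
    stop("Poisson's ratio nu must lie in [0, 0.5); nu = ", nu,
         " is an invalid or incompressible limit")
  c(mu_s = E / (2 * (1 + nu)),
    lambda_s = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

#' Recover elastic moduli from Lame parameters
#'
#' Inverse of [lame_from_elastic()]:
#' \eqn{E = \mu_s(3\lambda_s + 2\mu_s)/(\lambda_s + \mu_s)},
#' \eqn{\nu = \lambda_s / (2(\lambda_s + \mu_s))}.
#'
#' @param mu_s,lambda_s Lame parameters, `mu_s > 0`, `lambda_s >= 0`.
#' @return Named numeric vector with components `E` and `nu`.
#' @export
elastic_from_lame <- function(mu_s, lambda_s) {
  stopifnot(mu_s > 0, lambda_s >= 0)
  c(E = mu_s * (3 * lambda_s + 2 * mu_s) / (lambda_s + mu_s),
    nu = lambda_s / (2 * (lambda_s + mu_s)))
}

# All scalar fields of a parameter set, with their internal unit tags.
.param_units_internal <- c(
  E = "mmHg", nu = "-", mu_s = "mmHg", lambda_s = "mmHg",
  rho_f = "kg/cm3", rho_s = "kg/cm3",
  alpha = "-",
  kappa0 = "cm2/(day*mmHg)", mu_f = "-",
  phi0 = "-",
  d_p = "cm2/day", d_l = "cm2/day",
  chi = "cm2/(day*cell/cm3)",
  gamma_p = "1/day", lambda_lp = "1/(day*cell/cm3)",
  lambda_pl = "1/(day*cell/cm3)",
  pi_i = "mmHg", pi_c = "mmHg", sigma0 = "-",
  c_bp = "1/(cell/cm3)", P_c = "mmHg",
  L_p0 = "cm/(day*mmHg)", S_over_V = "1/cm",
  q0 = "1/day", k_m = "mmHg", n_hill = "-", v_max = "-",
  p0 = "mmHg", b = "-"
)

#' Construct and validate a model parameter set
#'
#' Collects every constant of the coupled poroelastic/immune model in one
#' place. Values are interpreted in the internal unit system
#' {cm, day, mmHg, cell/cm^3} unless a `units` vector declares otherwise,
#' in which case [normalize_units()] is applied. The Lame parameters are
#' always (re)derived from `E` and `nu`.
#'
#' `mu_f` is treated as a dimensionless scaling of the absolute
#' permeability, so `kappa0 / mu_f` is the Darcy mobility in
#' cm^2/(day mmHg). The body force `b` is carried as an always-zero
#' constant.
#'
#' @param values Named numeric vector or list covering the parameter fields
#'   (see [reference_parameters()] for the full roster). `mu_s`/`lambda_s`
#'   may be omitted; they are derived.
#' @param units Optional named character vector of source-unit tags for any
#'   subset of the fields (e.g. `c(q0 = "1/s")`). Unknown tags are an error.
#' @return An object of class `myo_params`: a named list of scalars with a
#'   `units` attribute holding internal unit tags.
#' @export
myo_parameters <- function(values, units = NULL) {
  values <- as.list(values)
  required <- setdiff(names(.param_units_internal), c("mu_s", "lambda_s", "b"))
  missing <- setdiff(required, names(values))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(values), names(.param_units_internal))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  if (is.null(values$b)) values$b <- 0
  utags <- .param_units_internal[names(values)]
  if (!is.null(units)) {
    bad <- setdiff(names(units), names(values))
    if (length(bad))
      stop("units given for unknown parameter(s): ", paste(bad, collapse = ", "))
    utags[names(units)] <- units
  }
  p <- structure(values, units = utags, class = "myo_params")
  p <- normalize_units(p)
  lame <- lame_from_elastic(p$E, p$nu)
  p$mu_s <- unname(lame["mu_s"])
  p$lambda_s <- unname(lame["lambda_s"])
  attr(p, "units")[c("mu_s", "lambda_s")] <- "mmHg"
  attr(p, "units") <- attr(p, "units")[names(p)]
  validate_parameters(p)
  p
}

#' Normalise a parameter set into the internal unit system
#'
#' Converts every field carrying a recognised source-unit tag into
#' {cm, day, mmHg, cell/cm^3}: per-second rates are multiplied by 86400
#' and pressures printed in kg/(cm s^2) are divided by 1.33322. Values
#' already tagged with an internal unit pass through unchanged, so the
#' operation is idempotent.
#'
#' @param p A `myo_params` object (or plain named list with a `units`
#'   attribute).
#' @return The parameter set with all fields in internal units.
#' @export
normalize_units <- function(p) {
  utags <- attr(p, "units")
  if (is.null(utags)) stop("parameter set carries no unit declarations")
  for (nm in names(p)) {
    tag <- utags[[nm]]
    if (!tag %in% names(.unit_table))
      stop("unknown unit tag '", tag, "' for parameter '", nm, "'")
    p[[nm]] <- p[[nm]] * .unit_table[[tag]]
    utags[[nm]] <- .param_units_internal[[nm]]
  }
  attr(p, "units") <- utags
  p
}

#' @keywords internal
validate_parameters <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameters: ", msg)
  chk(p$E > 0, "E must be positive")
  chk(p$nu > 0 && p$nu < 0.5, "nu must lie in (0, 0.5)")
  chk(p$phi0 > 0 && p$phi0 < 1, "phi0 must lie in (0, 1)")
  chk(p$sigma0 >= 0 && p$sigma0 <= 1, "sigma0 must lie in [0, 1]")
  chk(p$n_hill >= 1, "Hill coefficient must be >= 1")
  rates <- c("d_p", "d_l", "gamma_p", "lambda_lp", "lambda_pl",
             "q0", "L_p0", "kappa0", "chi", "c_bp", "v_max")
  for (r in rates) chk(p[[r]] >= 0, paste(r, "must be nonnegative"))
  lame <- lame_from_elastic(p$E, p$nu)
  chk(abs(p$mu_s - lame["mu_s"]) <= 1e-10 * abs(lame["mu_s"]) &&
        abs(p$lambda_s - lame["lambda_s"]) <=
          1e-10 * max(abs(lame["lambda_s"]), 1e-300),
      "mu_s/lambda_s inconsistent with E, nu")
  invisible(p)
}

# Table of reference values as printed (source units), shared by all presets.
.reference_raw <- function() {
  list(
    values = list(
      E = 60, nu = 0.35,
      rho_f = 1e-3, rho_s = 2e-3,
      alpha = 0.25,
      chi = 1e-2,
      lambda_lp = 1.5,
      pi_i = 10, pi_c = 20,
      sigma0 = 0.91,
      c_bp = 1e4,
      P_c = 20,
      L_p0 = 3.6e-8,
      q0 = 6.82e-5,
      k_m = 6.5, n_hill = 1, v_max = 200,
      kappa0 = 2.5e-7,
      mu_f = 1,
      S_over_V = 174,
      phi0 = 0.2,
      p0 = 0,
      # preset-dependent, filled below
      d_p = NA_real_, d_l = NA_real_, lambda_pl = NA_real_, gamma_p = NA_real_
    ),
    units = c(E = "kg/(cm*s2)", L_p0 = "cm/(s*mmHg)", q0 = "1/s",
              kappa0 = "cm2/(s*mmHg)")
  )
}

# preset columns: d_p, d_l [cm^2/day], lambda_pl [1/(day cell/cm3)],
# gamma_p [1/day]
.preset_table <- list(
  "local-1d"   = c(d_p = 1e-3, d_l = 5e-2, lambda_pl = 2.1,    gamma_p = 9.0e-2),
  "diffuse-1d" = c(d_p = 5e-3, d_l = 5e-2, lambda_pl = 1e-1,   gamma_p = 3e-2),
  "local-3d"   = c(d_p = 5e-4, d_l = 5e-1, lambda_pl = 1.2e-1, gamma_p = 9.0),
  "diffuse-3d" = c(d_p = 1e-3, d_l = 3e-2, lambda_pl = 5e-2,   gamma_p = 6e-2)
)

#' Reference parameter presets for local and diffuse myocarditis
#'
#' Returns the full reference parameter set, with the pathogen/leukocyte
#' diffusivities, the leukocyte migration rate and the net pathogen
#' reproduction rate taken from the requested scenario column. All values
#' are normalised to the internal unit system {cm, day, mmHg, cell/cm^3}.
#'
#' @param preset One of `"local-1d"`, `"diffuse-1d"`, `"local-3d"`,
#'   `"diffuse-3d"`.
#' @return A `myo_params` object.
#' @examples
#' p <- reference_parameters("local-1d")
#' p$gamma_p   # 0.09 per day
#' @export
reference_parameters <- function(preset = c("local-1d", "diffuse-1d",
                                            "local-3d", "diffuse-3d")) {
  if (length(preset) != 1L || !preset %in% names(.preset_table))
    stop("unknown preset '", paste(preset, collapse = ","),
         "'; valid presets: ", paste(names(.preset_table), collapse = ", "))
  raw <- .reference_raw()
  col <- .preset_table[[preset]]
  raw$values[names(col)] <- as.list(col)
  p <- myo_parameters(raw$values, units = raw$units)
  attr(p, "preset") <- preset
  p
}

#' Update one parameter, keeping derived fields consistent
#'
#' Changing `E` or `nu` re-derives the Lame parameters; changing anything
#' else is a plain replacement. Used by the sensitivity driver so that a
#' scaled Young's modulus propagates into the stress law.
#'
#' @param p A `myo_params` object.
#' @param name Field name.
#' @param value New value (internal units).
#' @return The modified parameter set.
#' @export
set_parameter <- function(p, name, value) {
  if (!name %in% names(p)) stop("unknown parameter '", name, "'")
  p[[name]] <- value
  if (name %in% c("E", "nu")) {
    lame <- lame_from_elastic(p$E, p$nu)
    p$mu_s <- unname(lame["mu_s"])
    p$lambda_s <- unname(lame["lambda_s"])
  }
  validate_parameters(p)
  p
}

#' @export
print.myo_params <- function(x, ...) {
  preset <- attr(x, "preset")
  cat("Myocarditis model parameters",
      if (!is.null(preset)) paste0(" (preset: ", preset, ")"), "\n", sep = "")
  u <- attr(x, "units")
  for (nm in names(x))
    cat(sprintf("  %-10s %12.6g  [%s]\n", nm, x[[nm]], u[[nm]]))
  invisible(x)
}

#' Write a parameter set to a plain-text key:value file
#'
#' @param p A `myo_params` object.
#' @param path Output file path.
#' @export
write_parameters <- function(p, path) {
  lines <- vapply(names(p), function(nm)
    sprintf("%s: %.17g", nm, p[[nm]]), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set from a plain-text key:value file
#'
#' Values are assumed to be in internal units (as written by
#' [write_parameters()]).
#'
#' @param path File path.
#' @return A `myo_params` object.
#' @export
read_parameters <- function(path) {
  kv <- .read_keyvalue(path)
  vals <- lapply(kv, function(s) as.numeric(s))
  myo_parameters(vals)
}

# shared key:value reader ("key: value" or "key = value", '#' comments)
.read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:=]+)[:=](.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: '", ln, "'")
    out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}
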