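# Capillary/lymphatic fluid exchange and immune reaction kinetics.
#
# The interstitial fluid source is
#   l(p, c_p) = C_f(c_p) [p_c - p - sigma(c_p) (pi_c - pi_i)]
#               - q0 [1 + v_max (p - p0)^n / (k_m^n + (p - p0)^n)]
# with C_f(c_p) = (S/V) L_p0 (1 + c_bp c_p) and
# sigma(c_p) = sigma0 / (1 + c_bp c_p). Pathogen presence therefore both
# raises the wall conductivity and erodes the oncotic gradient, producing
# net filtration; rising interstitial pressure recruits lymphatic drainage
# through the Hill term. For p < p0 the Hill fraction is clamped to zero:
# lymph flow never falls below its resting value q0.

#' Capillary wall conductivity as a function of pathogen concentration
#'
#' @param c_p Pathogen concentration (cell/cm^3), >= 0.
#' @param params A `myo_params` object.
#' @return Conductivity (S/V) L_p0 (1 + c_bp c_p) in 1/(day mmHg).
#' @export
capillary_conductivity <- function(c_p, params) {
  if (any(c_p < 0)) stop("pathogen concentration must be nonnegative")
  params$S_over_V * params$L_p0 * (1 + params$c_bp * c_p)
}

#' Osmotic reflection coefficient as a function of pathogen concentration
#'
#' @inheritParams capillary_conductivity
#' @return sigma0 / (1 + c_bp c_p), dimensionless, decreasing in `c_p`.
#' @export
reflection_coefficient <- function(c_p, params) {
  if (any(c_p < 0)) stop("pathogen concentration must be nonnegative")
  params$sigma0 / (1 + params$c_bp * c_p)
}

#' Lymphatic drainage rate (Hill saturation in pressure)
#'
#' \eqn{q(p) = q_0 [1 + v_{max} (p-p_0)^n / (k_m^n + (p-p_0)^n)]} for
#' `p >= p0`; below the resting pressure the Hill fraction is clamped to
#' zero so drainage stays at `q0`.
#'
#' @param p Interstitial fluid pressure (mmHg).
#' @param params A `myo_params` object.
#' @return Volumetric drainage rate (1/day).
#' @export
lymphatic_flow <- function(p, params) {
  dp <- pmax(p - params$p0, 0)
  hill <- dp^params$n_hill / (params$k_m^params$n_hill + dp^params$n_hill)
  hill[dp == 0] <- 0  # guards 0/0 when k_m = 0
  params$q0 * (1 + params$v_max * hill)
}

#' Interstitial fluid exchange (Starling filtration minus lymph drainage)
#'
#' @param p Interstitial fluid pressure (mmHg).
#' @param c_p Pathogen concentration (cell/cm^3), >= 0.
#' @param params A `myo_params` object.
#' @return List of class `myo_exchange` with elements `capillary_flow`,
#'   `lymph_flow`, `total` (= capillary - lymph, 1/day), `C_f` and `sigma`.
#' @examples
#' ex <- fluid_exchange(0, 0, reference_parameters("local-1d"))
#' ex$total  # near-homeostasis: |total| << q0
#' @export
fluid_exchange <- function(p, c_p, params) {
  if (any(c_p < 0)) stop("pathogen concentration must be nonnegative")
  C_f <- capillary_conductivity(c_p, params)
  sigma <- reflection_coefficient(c_p, params)
  cap <- C_f * (params$P_c - p - sigma * (params$pi_c - params$pi_i))
  lymph <- lymphatic_flow(p, params)
  structure(list(capillary_flow = cap, lymph_flow = lymph,
                 total = cap - lymph, C_f = C_f, sigma = sigma),
            class = "myo_exchange")
}

#' Pathogen net reaction rate
#'
#' Net reproduction minus phagocytosis,
#' \eqn{r_p = \phi_f (\gamma_p - \lambda_{lp} c_l) c_p}, expressed per unit
#' fluid fraction `phi_f`. Zero pathogen concentration is a fixed point.
#'
#' @param phi_f Fluid phase fraction in (0, 1).
#' @param c_p,c_l Pathogen and leukocyte concentrations, >= 0.
#' @param params A `myo_params` object.
#' @return Reaction rate (cell/cm^3 per day).
#' @export
pathogen_reaction <- function(phi_f, c_p, c_l, params) {
  if (any(phi_f <= 0 | phi_f >= 1)) stop("phi_f must lie in (0, 1)")
  if (any(c_p < 0) || any(c_l < 0)) stop("concentrations must be nonnegative")
  phi_f * (params$gamma_p - params$lambda_lp * c_l) * c_p
}

#' Leukocyte recruitment rate
#'
#' \eqn{r_l = \lambda_{pl} c_p c_l}: migration from the bloodstream is
#' proportional to both the local pathogen load and the leukocytes already
#' present. Zero leukocyte concentration is a fixed point.
#'
#' @inheritParams pathogen_reaction
#' @return Reaction rate (cell/cm^3 per day), nonnegative.
#' @export
leukocyte_reaction <- function(c_p, c_l, params) {
  if (any(c_p < 0) || any(c_l < 0)) stop("concentrations must be nonnegative")
  params$lambda_pl * c_p * c_l
}
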