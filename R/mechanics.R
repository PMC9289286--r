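# Finite-strain kinematics and neo-Hookean constitutive law, 1D reduction.
#
# In one dimension every tensor is a scalar: F = 1 + du/dX, J = F,
# F^{-t} = F^{-1} and J F^{-1} = 1, so the pore-pressure contribution to
# the total first Piola-Kirchhoff stress reduces to -alpha * p.

#' 1D deformation gradient and Jacobian
#'
#' @param du_dx Displacement gradient(s), must exceed -1 (J > 0).
#' @return List with fields `du_dx`, `F` and `J` (vectors of the input
#'   length), class `myo_kinematics`.
#' @examples
#' deformation_gradient_1d(0.1)$J  # 1.1
#' @export
deformation_gradient_1d <- function(du_dx) {
  if (any(!is.finite(du_dx)))
    stop("non-finite displacement gradient")
  if (any(du_dx <= -1))
    stop("kinematic violation: du/dx <= -1 gives J <= 0 (interpenetration)")
  F <- 1 + du_dx
  structure(list(du_dx = du_dx, F = F, J = F), class = "myo_kinematics")
}

#' Effective (skeleton) first Piola-Kirchhoff stress, 1D neo-Hookean
#'
#' \eqn{P_{eff} = \mu_s (F - F^{-1}) + \lambda_s \ln(J) F^{-1}} with
#' \eqn{J = F}. Vanishes at the reference state F = 1 and is strictly
#' increasing in F for positive Lame parameters.
#'
#' @param F Deformation gradient(s), > 0.
#' @param mu_s,lambda_s Lame parameters (pressure units).
#' @return Stress in the same pressure units.
#' @export
effective_stress_1d <- function(F, mu_s, lambda_s) {
  if (any(!is.finite(F)) || any(F <= 0))
    stop("deformation gradient must be positive and finite")
  mu_s * (F - 1 / F) + lambda_s * log(F) / F
}

# dP_eff/dF, used by the mechanics linearisation and the static inversion
.effective_stress_deriv_1d <- function(F, mu_s, lambda_s) {
  mu_s * (1 + 1 / F^2) + lambda_s * (1 - log(F)) / F^2
}

#' Total first Piola-Kirchhoff stress in 1D
#'
#' \eqn{P = P_{eff} - \alpha p J F^{-1} = P_{eff} - \alpha p} since
#' \eqn{J F^{-1} = 1} in one dimension.
#'
#' @param P_eff Effective stress.
#' @param alpha Biot-Willis modulus.
#' @param p Pore fluid pressure.
#' @param F Deformation gradient (> 0); retained for interface symmetry,
#'   the 1D reduction does not use it beyond the positivity check.
#' @return Total stress.
#' @export
total_stress_1d <- function(P_eff, alpha, p, F = 1) {
  if (any(F <= 0)) stop("deformation gradient must be positive")
  P_eff - alpha * p
}
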