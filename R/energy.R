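#' Strain energy per unit mass of elastin
#'
#' Nearly incompressible neo-Hookean:
#' `W = mu/2 (I1_bar - 3) + kappa/2 (J_el - 1)^2` with `I1_bar` the first
#' invariant of the isochoric elastic Cauchy-Green tensor.
#'
#' @param F_el Elastic deformation gradient of elastin (3x3).
#' @param p An [elastin_params()] object.
#' @return Energy per unit mass (J/kg).
#' @export
elastin_energy <- function(F_el, p) {
  J_el <- det(F_el)
  I1_bar <- J_el^(-2 / 3) * sum(F_el^2)
  p$mu_e / 2 * (I1_bar - 3) + p$kappa / 2 * (J_el - 1)^2
}

#' Strain energy per unit mass of a Fung-type fiber constituent
#'
#' `W = k1/(2 k2) (exp(k2 (I4 - 1)^2) - 1)` with the tension/compression
#' parameter switch on `I4 >= 1`.
#'
#' @param I4 Fourth invariant (squared elastic fiber stretch).
#' @param p A [fiber_params()] object.
#' @return Energy per unit mass (J/kg).
#' @export
fiber_energy <- function(I4, p) {
  k <- fiber_k(I4, p)
  k$k1 / (2 * k$k2) * (exp(k$k2 * (I4 - 1)^2) - 1)
}

#' Active strain energy per unit mass of smooth muscle
#'
#' The exact hyperelastic potential of the active Cauchy stress: its
#' derivative through `lambda_act = |F a0|/lambda0_m` reproduces
#' `sigma_act = (rho_m/rho0(0)) sigma_act_max f(lambda_act)
#' (Fa0)(x)(Fa0)/|Fa0|^2` with the inverted-parabola factor `f`. In closed
#' form, with `d = lambda_max - lambda_zero`,
#' `W_act = (sigma_act_max/rho0(0)) [ (1 - lambda_max^2/d^2) log(l)
#'  + 2 lambda_max l / d^2 - l^2 / (2 d^2) ]`.
#' When clamping is active the potential continues constant outside the
#' interval where `f > 0`.
#'
#' @param lambda_act Active stretch (vectorized).
#' @param p An [active_params()] object.
#' @param rho0_total_init Initial total referential mixture density (kg/m^3).
#' @return Energy per unit mass (J/kg).
#' @export
active_energy <- function(lambda_act, p, rho0_total_init) {
  d <- p$lambda_max - p$lambda_zero
  A <- function(l) {
    (1 - p$lambda_max^2 / d^2) * log(l) +
      2 * p$lambda_max * l / d^2 - l^2 / (2 * d^2)
  }
  l <- lambda_act
  if (p$clamp_negative) {
    lo <- p$lambda_zero
    hi <- 2 * p$lambda_max - p$lambda_zero
    l <- pmin(pmax(l, lo), hi)
  }
  p$sigma_act_max / rho0_total_init * A(l)
}

#' Total strain energy per unit reference volume at a material point
#'
#' Mixture energy `W = rho0_e W_e + sum_j rho0_cj W_cj + rho0_m (W_m,pass +
#' W_act)` (J/m^3). Used by the finite-difference energy-consistency checks:
#' the mixture Cauchy stress equals `(1/J) (dW/dF) F^T`.
#'
#' @param point A [material_point()].
#' @param F Total deformation gradient (3x3).
#' @param params A [mixture_params()] object.
#' @return Energy per unit reference volume (J/m^3).
#' @export
point_strain_energy <- function(point, F, params) {
  Fg <- growth_tensor(point)
  Fel_e <- elastic_deformation(F, Fg, elastin_remodeling_tensor(point))
  W <- point$rho_e * elastin_energy(Fel_e, params$elastin)
  for (j in seq_len(4)) {
    a0 <- fiber_direction(params$collagen_angles[j])
    Fr <- remodeling_tensor(point$lam_r_c[j], a0)
    I4 <- fiber_fourth_invariant(F, a0, Fg, Fr)
    W <- W + point$rho_c[j] * fiber_energy(I4, params$collagen)
  }
  a0m <- fiber_direction(params$smc_angle)
  Frm <- remodeling_tensor(point$lam_r_m, a0m)
  I4m <- fiber_fourth_invariant(F, a0m, Fg, Frm)
  lam_act <- sqrt(sum((F %*% a0m)^2)) / params$smc$lambda0
  W + point$rho_m * (fiber_energy(I4m, params$smc) +
                       active_energy(lam_act, params$active,
                                     point$rho_tot_init))
}
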