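#' Cauchy stress of elastin (nearly incompressible neo-Hookean)
#'
#' Deviatoric term scaled by the current spatial density
#' `rho0_e(t) / (J_el J_gr)` and volumetric penalty scaled by
#' `rho0_e(t) / J_gr`:
#' `sigma = rho_e mu J_el^(-2/3) (B_el - tr(B_el)/3 I) +
#'  (rho0_e/J_gr) kappa (J_el - 1) I`.
#' Both coefficients are exactly the push-forward of the energy derivative
#' `2 dW/dC`, so the stress is energy-consistent to machine precision.
#'
#' @param F_el Elastic deformation gradient of elastin (3x3).
#' @param rho0_e_t Current referential elastin density (kg/m^3).
#' @param J_gr_e Determinant of elastin's inelastic deformation `F_r F_g`.
#' @param p An [elastin_params()] object.
#' @return Cauchy stress (3x3, Pa).
#' @export
elastin_cauchy_stress <- function(F_el, rho0_e_t, J_gr_e, p) {
  J_el <- det(F_el)
  if (!is.finite(J_el) || J_el <= 0) {
    stop("`F_el` must have positive determinant.", call. = FALSE)
  }
  B <- F_el %*% t(F_el)
  J <- J_el * J_gr_e
  dev <- (rho0_e_t / J) * p$mu_e * J_el^(-2 / 3) *
    (B - (sum(diag(B)) / 3) * diag(3))
  vol <- (rho0_e_t / J_gr_e) * p$kappa * (J_el - 1) * diag(3)
  dev + vol
}

#' Passive Cauchy stress of a fiber constituent (Fung-type)
#'
#' `sigma = 2 rho(t) k1 (I4-1) exp(k2 (I4-1)^2) (F a0)(x)(F a0) /
#' |F_gr a0|^2` with `rho(t) = rho0(t)/det(F)` the current spatial density
#' and the tension/compression parameter switch decided on `I4 >= 1`.
#'
#' @param F Total deformation gradient (3x3).
#' @param a0 Unit reference fiber direction.
#' @param rho0_t Current referential density of the constituent (kg/m^3).
#' @param p A [fiber_params()] object.
#' @param F_g,F_r Growth and remodeling parts (3x3), default identity.
#' @return Cauchy stress (3x3, Pa); rank-one with axis `F a0`.
#' @export
fiber_passive_cauchy_stress <- function(F, a0, rho0_t, p,
                                        F_g = diag(3), F_r = diag(3)) {
  a0 <- a0 / sqrt(sum(a0^2))
  Fgr <- F_r %*% F_g
  nf2 <- sum((Fgr %*% a0)^2)
  I4 <- sum((F %*% a0)^2) / nf2
  k <- fiber_k(I4, p)
  x <- I4 - 1
  fa <- drop(F %*% a0)
  (2 * (rho0_t / det(F)) * k$k1 * x * exp(k$k2 * x^2) / nf2) * outer(fa, fa)
}

#' Length-tension factor of the smooth muscle active stress
#'
#' Inverted parabola `f = 1 - (lambda_max - lambda_act)^2 /
#' (lambda_max - lambda_zero)^2`, equal to 1 at `lambda_max` and 0 at
#' `lambda_zero`; negative values are clamped to zero when
#' `p$clamp_negative` is set (the default).
#'
#' @param lambda_act Active stretch (vectorized).
#' @param p An [active_params()] object.
#' @return Dimensionless factor(s), at most 1; clamped to be non-negative
#'   by default.
#' @export
active_stress_factor <- function(lambda_act, p) {
  d <- p$lambda_max - p$lambda_zero
  f <- 1 - (p$lambda_max - lambda_act)^2 / d^2
  if (p$clamp_negative) f <- pmax(f, 0)
  f
}

#' Active Cauchy stress of smooth muscle cells
#'
#' `sigma_act = (rho_m(t)/rho0(0)) sigma_act_max f(lambda_m/lambda0_m)
#' (F a0)(x)(F a0) / |F a0|^2` where `lambda_m = |F a0|` is the total SMC
#' stretch (the active stretch tracks tissue dilation: SMCs are assumed not
#' to remodel their contractile apparatus), `rho_m(t) = rho0_m(t)/det(F)` and
#' `rho0(0)` is the initial total mixture density at the point.
#'
#' @param F Total deformation gradient (3x3).
#' @param a0 Unit SMC fiber direction.
#' @param rho0_m_t Current referential SMC density (kg/m^3).
#' @param rho0_total_init Initial total referential mixture density (kg/m^3).
#' @param p An [active_params()] object.
#' @param lambda0_m SMC deposition stretch (divides the total stretch to give
#'   the active stretch).
#' @return Cauchy stress (3x3, Pa).
#' @export
smc_active_cauchy_stress <- function(F, a0, rho0_m_t, rho0_total_init, p,
                                     lambda0_m = 1.1) {
  a0 <- a0 / sqrt(sum(a0^2))
  fa <- drop(F %*% a0)
  lm2 <- sum(fa^2)
  f <- active_stress_factor(sqrt(lm2) / lambda0_m, p)
  ((rho0_m_t / det(F)) / rho0_total_init * p$sigma_act_max * f / lm2) *
    outer(fa, fa)
}

# per-unit-mass along-fiber 2nd Piola-Kirchhoff stress measure and its
# stiffness; the scalar pair used by the remodeling law
fiber_pk2_per_mass <- function(lambda_el, p) {
  I4 <- lambda_el^2
  k <- fiber_k(I4, p)
  x <- I4 - 1
  2 * k$k1 * x * exp(k$k2 * x^2)
}

fiber_pk2_stiffness <- function(lambda_el, p) {
  I4 <- lambda_el^2
  k <- fiber_k(I4, p)
  x <- I4 - 1
  # d/dlambda_el of 2 k1 x exp(k2 x^2), x = lambda_el^2 - 1
  2 * k$k1 * exp(k$k2 * x^2) * (1 + 2 * k$k2 * x^2) * 2 * lambda_el
}
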