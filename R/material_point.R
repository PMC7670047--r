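#' Construct a material point of the constrained mixture
#'
#' A material point carries the per-constituent referential densities, the
#' elastin deposition tensor (diagonal in the local frame), the along-fiber
#' remodeling stretches of the fiber constituents, the radial growth stretch,
#' and the homeostatic bookkeeping (initial densities, homeostatic target
#' stresses, deposition pre-stress scalars).
#'
#' Remodeling stretches start at `1/lambda0` so every fiber constituent is
#' born at its deposition stretch; the elastin remodeling tensor is frozen at
#' `G_h^-1` (elastin does not remodel).
#'
#' @param params A [mixture_params()] object.
#' @param layer `"media"` or `"adventitia"`.
#' @param rho_e,rho_c,rho_m Referential densities (kg/m^3): elastin scalar,
#'   collagen length-4, SMC scalar. Defaults are the whole-wall values in
#'   `params` (no layer allocation).
#' @param lambda0_et Initial circumferential elastin deposition stretch (the
#'   radial component follows from unit determinant; homeostatic
#'   initialization later re-sets the full diagonal).
#' @return A list with class `"material_point"`.
#' @export
material_point <- function(params, layer = c("media", "adventitia"),
                           rho_e = params$rho0_elastin,
                           rho_c = params$rho0_collagen *
                             params$collagen_fractions,
                           rho_m = params$rho0_smc,
                           lambda0_et = 1) {
  layer <- match.arg(layer)
  stopifnot(rho_e >= 0, all(rho_c >= 0), rho_m >= 0, length(rho_c) == 4)
  lz <- params$elastin$lambda0_z
  gh <- c(1 / (lambda0_et * lz), lambda0_et, lz)
  pt <- structure(list(
    layer = layer,
    rho_e = rho_e, rho_c = rho_c, rho_m = rho_m,
    gh_e = gh,
    lam_r_c = rep(1 / params$collagen$lambda0, 4),
    lam_r_m = 1 / params$smc$lambda0,
    g_rr = 1,
    rho_e_init = rho_e,
    rho_tot_init = rho_e + sum(rho_c) + rho_m,
    sig_h_m = NA_real_, sig_h_c = rep(NA_real_, 4),
    s_pre_c = rep(NA_real_, 4), s_pre_m = NA_real_
  ), class = "material_point")
  set_homeostatic_targets(pt, params)
}

# unit fiber direction in the (r, theta, z) frame for an angle measured from
# the circumferential direction
fiber_direction <- function(angle) c(0, cos(angle), sin(angle))

# growth tensor of a point (rank-one radial)
growth_tensor <- function(point) diag(c(point$g_rr, 1, 1))

# elastin remodeling tensor: frozen at the inverse deposition stretch
elastin_remodeling_tensor <- function(point) diag(1 / point$gh_e)

#' Record homeostatic targets and deposition pre-stresses at a point
#'
#' Evaluates the constituent fiber stresses of the point under the total
#' deformation `F` and stores them as the homeostatic targets of the
#' mass-production law, together with the per-unit-mass along-fiber
#' second Piola-Kirchhoff deposition pre-stress of each fiber constituent.
#'
#' @param point A [material_point()].
#' @param params A [mixture_params()] object.
#' @param F Total deformation gradient defining homeostasis (default
#'   identity: the loaded in-vivo reference).
#' @return The updated point.
#' @export
set_homeostatic_targets <- function(point, params, F = diag(3)) {
  st <- constituent_stresses(point, F, params)
  point$sig_h_c <- st$fiber_stress_c
  point$sig_h_m <- if (params$smc_drive_includes_active) {
    st$fiber_stress_m_total
  } else {
    st$fiber_stress_m_passive
  }
  point$s_pre_c <- vapply(seq_len(4), function(j) {
    fiber_pk2_per_mass(st$lambda_el_c[j], params$collagen)
  }, numeric(1))
  point$s_pre_m <- fiber_pk2_per_mass(st$lambda_el_m, params$smc)
  point
}

#' Per-constituent Cauchy stresses at a material point
#'
#' Evaluates elastin, the four collagen families and the SMC passive and
#' active Cauchy stress tensors under a total deformation gradient `F`,
#' together with the along-fiber scalar stresses used by the growth and
#' remodeling laws.
#'
#' @param point A [material_point()].
#' @param F Total deformation gradient (3x3).
#' @param params A [mixture_params()] object.
#' @return A list with tensors `elastin`, `collagen` (list of 4),
#'   `smc_passive`, `smc_active`, `total`, scalar fiber Cauchy stresses
#'   `fiber_stress_c`, `fiber_stress_m_passive`, `fiber_stress_m_total`
#'   (Pa), elastic fiber stretches `lambda_el_c`, `lambda_el_m`, the total
#'   SMC stretch `lambda_m` and the active factor `f_act`.
#' @export
constituent_stresses <- function(point, F, params) {
  Fg <- growth_tensor(point)
  # elastin
  Fel_e <- elastic_deformation(F, Fg, elastin_remodeling_tensor(point))
  J_gr_e <- det(Fg) / prod(point$gh_e)
  sig_e <- elastin_cauchy_stress(Fel_e, point$rho_e, J_gr_e, params$elastin)
  # collagen families
  sig_c <- vector("list", 4)
  fib_c <- lam_el_c <- numeric(4)
  for (j in seq_len(4)) {
    a0 <- fiber_direction(params$collagen_angles[j])
    Fr <- remodeling_tensor(point$lam_r_c[j], a0)
    sig_c[[j]] <- fiber_passive_cauchy_stress(F, a0, point$rho_c[j],
                                              params$collagen, Fg, Fr)
    I4 <- fiber_fourth_invariant(F, a0, Fg, Fr)
    lam_el_c[j] <- sqrt(I4)
    # specific (per-unit-mass) fiber stress driving mass turnover
    fib_c[j] <- fiber_pk2_per_mass(lam_el_c[j], params$collagen) * I4
  }
  # SMC
  a0m <- fiber_direction(params$smc_angle)
  Frm <- remodeling_tensor(point$lam_r_m, a0m)
  sig_mp <- fiber_passive_cauchy_stress(F, a0m, point$rho_m, params$smc,
                                        Fg, Frm)
  sig_ma <- smc_active_cauchy_stress(F, a0m, point$rho_m, point$rho_tot_init,
                                     params$active, params$smc$lambda0)
  lam_m <- sqrt(sum((F %*% a0m)^2))
  lam_el_m <- sqrt(fiber_fourth_invariant(F, a0m, Fg, Frm))
  fib_mp <- fiber_pk2_per_mass(lam_el_m, params$smc) * lam_el_m^2
  fib_ma <- params$active$sigma_act_max *
    active_stress_factor(lam_m / params$smc$lambda0, params$active) /
    point$rho_tot_init
  total <- sig_e + Reduce(`+`, sig_c) + sig_mp + sig_ma
  list(elastin = sig_e, collagen = sig_c, smc_passive = sig_mp,
       smc_active = sig_ma, total = total,
       fiber_stress_c = fib_c,
       fiber_stress_m_passive = fib_mp,
       fiber_stress_m_total = fib_mp + fib_ma,
       lambda_el_c = lam_el_c, lambda_el_m = lam_el_m, lambda_m = lam_m,
       f_act = active_stress_factor(lam_m / params$smc$lambda0,
                                    params$active))
}

#' Mixture Cauchy stress at a material point
#'
#' Sum of the elastin, collagen-family and SMC (passive + active) Cauchy
#' stress contributions; linear in each constituent's density.
#'
#' @inheritParams constituent_stresses
#' @return Cauchy stress tensor (3x3, Pa).
#' @export
mixture_cauchy_stress <- function(point, F, params) {
  constituent_stresses(point, F, params)$total
}
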