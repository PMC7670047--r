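#' Elastin degradation rate
#'
#' Background turnover plus a localized damage pulse:
#' `rate = -rho/T_e - w (D_max/t_dam) rho_init exp(-t/t_dam)` (kg/m^3/day),
#' always non-positive. The spatial weight `w` in `[0, 1]` localizes the
#' damage axially; `w = 1` reproduces the pointwise law verbatim.
#'
#' @param t Time since damage onset (days).
#' @param rho0_e_t Current referential elastin density (kg/m^3).
#' @param rho0_e_init Initial referential elastin density (kg/m^3).
#' @param p An [elastin_params()] object (supplies `T_e_days`).
#' @param d A [damage_params()] object.
#' @param spatial_weight Damage weight in `[0, 1]`.
#' @return Degradation rate (kg/m^3/day), vectorized over densities.
#' @export
elastin_degradation_rate <- function(t, rho0_e_t, rho0_e_init, p, d,
                                     spatial_weight = 1) {
  stopifnot(t >= 0, all(spatial_weight >= 0), all(spatial_weight <= 1))
  base <- -rho0_e_t / p$T_e_days
  if (!d$enabled || d$D_max == 0) {
    return(base)
  }
  base - spatial_weight * (d$D_max / d$t_dam) * rho0_e_init *
    exp(-t / d$t_dam)
}

# closed-form advance of the linear elastin density ODE over [t, t+dt];
# the damage pulse decays on the scale t_dam which can be shorter than the
# monthly step, so the forcing is integrated exactly rather than sampled
elastin_density_step <- function(t, dt, rho0_e_t, rho0_e_init, p, d,
                                 spatial_weight = 1) {
  a <- 1 / p$T_e_days                  # background rate (0 when T_e = Inf)
  out <- rho0_e_t * exp(-a * dt)
  if (!d$enabled || d$D_max == 0 || all(spatial_weight == 0)) {
    return(out)
  }
  b <- 1 / d$t_dam
  # integral of exp(-a(dt-s)) b exp(-b(t+s)) ds over s in [0, dt]
  conv <- if (abs(a - b) < 1e-12) {
    b * exp(-b * t) * exp(-a * dt) * dt
  } else {
    b * exp(-b * t) * exp(-a * dt) * (exp((a - b) * dt) - 1) / (a - b)
  }
  pmax(out - spatial_weight * d$D_max * rho0_e_init * conv, 0)
}

#' Stress-driven collagen mass production rate
#'
#' `rate = rho (k_sigma / T) (sigma_drive - target) / target` (kg/m^3/day):
#' net deposition when the driving fiber stress exceeds its homeostatic
#' target, net degradation below it. In the media the drive is the current
#' SMC fiber stress; in the adventitia each family's own fiber stress.
#'
#' @param sigma_drive Driving fiber Cauchy stress (Pa).
#' @param target Homeostatic fiber stress (Pa, > 0).
#' @param rho_cj Current referential collagen density (kg/m^3).
#' @param p A [fiber_params()] object (supplies `k_sigma`, `T_days`).
#' @return Production rate (kg/m^3/day), vectorized.
#' @export
collagen_production_rate <- function(sigma_drive, target, rho_cj, p) {
  if (any(!is.finite(target)) || any(target <= 0)) {
    stop("Homeostatic target stress must be positive and finite.",
         call. = FALSE)
  }
  rho_cj * (p$k_sigma / p$T_days) * (sigma_drive - target) / target
}

#' Along-fiber remodeling rate of a fiber constituent
#'
#' Scalar reduction of the homogenized remodeling law: turnover re-sets a
#' fiber's natural configuration so its stress relaxes toward the deposition
#' pre-stress at the rate `(rho_dot/rho + 1/T)`:
#' `lambda_r_dot = (rho_dot/rho + 1/T) (s - s_pre) lambda_r /
#'  (lambda_el ds/dlambda_el)`,
#' where `s(lambda_el)` is the per-unit-mass along-fiber second
#' Piola-Kirchhoff stress. Positive overstress produces inelastic
#' lengthening (`lambda_r_dot > 0`), which lowers the elastic stretch.
#'
#' @param lambda_el Current elastic fiber stretch.
#' @param lambda_r Current remodeling stretch.
#' @param s_pre Deposition pre-stress (per-unit-mass 2nd Piola-Kirchhoff).
#' @param rho_dot_over_rho Relative mass production rate (1/day).
#' @param p A [fiber_params()] object.
#' @return `d lambda_r / dt` (1/day), vectorized.
#' @export
remodeling_rate <- function(lambda_el, lambda_r, s_pre, rho_dot_over_rho, p) {
  s <- fiber_pk2_per_mass(lambda_el, p)
  stiff <- fiber_pk2_stiffness(lambda_el, p)
  if (any(abs(stiff) < 1e-12)) {
    stop("Vanishing fiber stiffness: remodeling rate is indeterminate.",
         call. = FALSE)
  }
  (rho_dot_over_rho + 1 / p$T_days) * (s - s_pre) * lambda_r /
    (lambda_el * stiff)
}

#' Growth tensor rate (rank-one radial volumetric growth)
#'
#' Mass added or removed changes the local reference volume through a
#' deformation aligned with the wall-thickness direction:
#' `F_g_dot = sum_i (rho_i_dot / rho0(t)) [F_g^-T : a_g(x)a_g]^-1 a_g(x)a_g`,
#' which keeps `det F_g` equal to `rho0(t)/rho0(0)` (added mass occupies
#' volume at the unchanged tissue density).
#'
#' @param rho_dots Referential mass production rates of all constituents
#'   (kg/m^3/day), summed internally.
#' @param rho0_total Current total referential density (kg/m^3).
#' @param F_g Current growth tensor (3x3).
#' @param a_g Unit growth direction (default radial).
#' @return `F_g_dot` (3x3, 1/day).
#' @export
growth_rate <- function(rho_dots, rho0_total, F_g, a_g = c(1, 0, 0)) {
  a_g <- a_g / sqrt(sum(a_g^2))
  P <- outer(a_g, a_g)
  coef <- sum(solve(t(F_g)) * P)   # F_g^-T : a_g (x) a_g
  (sum(rho_dots) / rho0_total) / coef * P
}

#' Advance a material point by one growth-and-remodeling step
#'
#' Staggered explicit update: the stresses of the incoming state (under the
#' supplied total deformation `F`) drive the density, remodeling and growth
#' rates, which are integrated over `dt` (forward Euler; the elastin damage
#' pulse is integrated in closed form because it can decay faster than the
#' step). Densities are floored at zero.
#'
#' @param point A [material_point()] with homeostatic targets recorded.
#' @param F Total deformation gradient at the point (3x3).
#' @param t Time since damage onset (days).
#' @param dt Time step (days).
#' @param d A [damage_params()] object.
#' @param params A [mixture_params()] object.
#' @param spatial_weight Damage weight in `[0, 1]` at this point.
#' @return The updated [material_point()].
#' @export
step_material_point <- function(point, F, t, dt, d, params,
                                spatial_weight = 1) {
  stopifnot(dt > 0)
  st <- constituent_stresses(point, F, params)
  if (any(!is.finite(unlist(st[c("fiber_stress_c", "fiber_stress_m_total")])))) {
    stop("Non-finite stresses at material point; cannot advance state.",
         call. = FALSE)
  }
  drive_m <- if (params$smc_drive_includes_active) {
    st$fiber_stress_m_total
  } else {
    st$fiber_stress_m_passive
  }
  rho_dot_c <- vapply(seq_len(4), function(j) {
    drive <- if (point$layer == "media") drive_m else st$fiber_stress_c[j]
    target <- if (point$layer == "media") point$sig_h_m else point$sig_h_c[j]
    collagen_production_rate(drive, target, point$rho_c[j], params$collagen)
  }, numeric(1))
  rho0_total <- point$rho_e + sum(point$rho_c) + point$rho_m
  # remodeling rates (elastin excluded; SMC density constant)
  new_lam_r_c <- point$lam_r_c
  for (j in seq_len(4)) {
    if (point$rho_c[j] > 0) {
      rr <- remodeling_rate(st$lambda_el_c[j], point$lam_r_c[j],
                            point$s_pre_c[j],
                            rho_dot_c[j] / point$rho_c[j], params$collagen)
      new_lam_r_c[j] <- point$lam_r_c[j] + dt * rr
    }
  }
  new_lam_r_m <- point$lam_r_m
  if (point$rho_m > 0) {
    rr_m <- remodeling_rate(st$lambda_el_m, point$lam_r_m, point$s_pre_m,
                            0, params$smc)
    new_lam_r_m <- point$lam_r_m + dt * rr_m
  }
  rho_e_new <- elastin_density_step(t, dt, point$rho_e, point$rho_e_init,
                                    params$elastin, d, spatial_weight)
  # effective elastin rate over the step keeps growth consistent with the
  # exactly integrated damage pulse
  rho_dot_e_eff <- (rho_e_new - point$rho_e) / dt
  Fg_dot <- growth_rate(c(rho_dot_e_eff, rho_dot_c, 0), rho0_total,
                        growth_tensor(point))
  point$g_rr <- point$g_rr + dt * Fg_dot[1, 1]
  point$rho_e <- rho_e_new
  point$rho_c <- pmax(point$rho_c + dt * rho_dot_c, 0)
  point$lam_r_c <- new_lam_r_c
  point$lam_r_m <- new_lam_r_m
  point
}
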