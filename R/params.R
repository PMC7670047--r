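#' Material parameters for one fiber-forming constituent
#'
#' Bundles the Fung-type exponential stiffness parameters (separate values in
#' tension and compression), the deposition stretch, the in-plane fiber angle,
#' the mass turnover time and the stress-gain of mass production for a single
#' collagen family or for the smooth muscle cells.
#'
#' @param k1_t,k2_t Fung parameters under tension. `k1_t` is a stress-like
#'   modulus per unit mass (J/kg), `k2_t` is dimensionless.
#' @param k1_c,k2_c Fung parameters under compression (same units).
#' @param lambda0 Deposition (pre-)stretch along the fiber, dimensionless.
#' @param angle Fiber angle in radians measured from the circumferential
#'   direction (0 = circumferential, pi/2 = axial).
#' @param T_days Average mass turnover time in days.
#' @param k_sigma Dimensionless gain of stress-driven mass production; the
#'   production rate constant is `k_sigma / T_days` per day.
#' @return A list with class `"fiber_params"`.
#' @export
fiber_params <- function(k1_t = 105, k2_t = 0.13, k1_c = 15, k2_c = 1,
                         lambda0 = 1.1, angle = 0, T_days = 101,
                         k_sigma = 0.05) {
  stopifnot(k1_t >= 0, k1_c >= 0, k2_t > 0, k2_c > 0,
            lambda0 > 0, T_days > 0, k_sigma >= 0)
  structure(list(k1_t = k1_t, k2_t = k2_t, k1_c = k1_c, k2_c = k2_c,
                 lambda0 = lambda0, angle = angle, T_days = T_days,
                 k_sigma = k_sigma),
            class = "fiber_params")
}

#' Elastin material parameters
#'
#' @param mu_e Shear modulus per unit mass (J/kg).
#' @param kappa Bulk modulus per unit mass (J/kg); the volumetric penalty.
#' @param lambda0_z Axial deposition stretch of elastin (dimensionless).
#' @param T_e_days Average elastin turnover time in days (use `Inf` to switch
#'   background degradation off).
#' @return A list with class `"elastin_params"`.
#' @export
elastin_params <- function(mu_e = 82, kappa = 100 * mu_e, lambda0_z = 1.3,
                           T_e_days = 101 * 365) {
  stopifnot(mu_e > 0, kappa > 0, lambda0_z > 0, T_e_days > 0)
  structure(list(mu_e = mu_e, kappa = kappa, lambda0_z = lambda0_z,
                 T_e_days = T_e_days),
            class = "elastin_params")
}

#' Smooth muscle active tone parameters
#'
#' The active Cauchy stress follows an inverted-parabola length-tension
#' relationship in the active stretch `lambda_act = lambda_m / lambda0_m`:
#' `sigma_act = sigma_act_max * (1 - (lambda_max - lambda_act)^2 /
#' (lambda_max - lambda_zero)^2)`, scaled by the local SMC mass fraction.
#'
#' @param sigma_act_max Maximal active Cauchy stress (Pa).
#' @param lambda_max Active stretch at maximal active stress.
#' @param lambda_zero Active stretch at zero active stress.
#' @param clamp_negative If `TRUE` (default) negative parabola values are
#'   clamped to zero: contracting cells cannot push.
#' @return A list with class `"active_params"`.
#' @export
active_params <- function(sigma_act_max = 54e3, lambda_max = 1.4,
                          lambda_zero = 0.8, clamp_negative = TRUE) {
  stopifnot(sigma_act_max >= 0)
  if (!(lambda_max > lambda_zero)) {
    stop("`lambda_max` must be strictly greater than `lambda_zero`.",
         call. = FALSE)
  }
  structure(list(sigma_act_max = sigma_act_max, lambda_max = lambda_max,
                 lambda_zero = lambda_zero,
                 clamp_negative = isTRUE(clamp_negative)),
            class = "active_params")
}

#' Damage (localized elastin degradation) parameters
#'
#' @param D_max Maximal damage: fraction of the initial elastin mass removed
#'   by the damage pulse at the center of the damaged region (0 to 1).
#' @param t_dam Temporal damage spread in days.
#' @param L_dam Spatial damage spread in meters; the per-ring damage weight is
#'   `exp(-(z/L_dam)^2)` with `z` the axial distance from `center`.
#' @param center Axial coordinate of the damage center (m).
#' @param enabled Logical; `FALSE` disables damage entirely.
#' @return A list with class `"damage_params"`.
#' @export
damage_params <- function(D_max = 0.5, t_dam = 40, L_dam = 0.01,
                          center = 0, enabled = TRUE) {
  stopifnot(D_max >= 0, D_max <= 1, t_dam > 0, L_dam > 0)
  structure(list(D_max = D_max, t_dam = t_dam, L_dam = L_dam,
                 center = center, enabled = isTRUE(enabled)),
            class = "damage_params")
}

#' Full constrained-mixture material parameter set
#'
#' Assembles elastin, four collagen fiber families, SMC passive and SMC active
#' parameters together with whole-wall densities and the media/adventitia
#' allocation fractions. All defaults are the calibrated human ascending
#' thoracic aorta values used throughout the package.
#'
#' @param elastin An [elastin_params()] object.
#' @param collagen A [fiber_params()] object shared by the four collagen
#'   families (their angles come from `collagen_angles`).
#' @param smc A [fiber_params()] object for the SMC passive response.
#' @param active An [active_params()] object.
#' @param rho0_elastin,rho0_collagen,rho0_smc Whole-wall referential densities
#'   (kg/m^3). `rho0_collagen` is the total over all families.
#' @param collagen_fractions Length-4 vector splitting `rho0_collagen` over
#'   the families; defaults to equal quarters.
#' @param collagen_angles Fiber angles (radians from circumferential) of the
#'   four collagen families: circumferential, axial, two diagonals.
#' @param smc_angle SMC fiber angle; circumferential by default.
#' @param alloc Layer allocation fractions of each constituent's total mass
#'   assigned to the media (remainder to the adventitia): named list with
#'   `elastin`, `smc`, `collagen_circ`, `collagen_other`.
#' @param smc_drive_includes_active Logical; if `TRUE` (default) the SMC
#'   stress driving medial collagen production is the total (passive +
#'   active) fiber stress.
#' @return A list with class `"mixture_params"`.
#' @export
mixture_params <- function(elastin = elastin_params(),
                           collagen = fiber_params(k1_t = 105, k2_t = 0.13),
                           smc = fiber_params(k1_t = 10, k2_t = 0.1),
                           active = active_params(),
                           rho0_elastin = 250,
                           rho0_collagen = 460,
                           rho0_smc = 280,
                           collagen_fractions = rep(0.25, 4),
                           collagen_angles = c(0, pi / 2, pi / 4, -pi / 4),
                           smc_angle = 0,
                           alloc = list(elastin = 0.97, smc = 1,
                                        collagen_circ = 0,
                                        collagen_other = 0.15),
                           smc_drive_includes_active = TRUE) {
  stopifnot(inherits(elastin, "elastin_params"),
            inherits(collagen, "fiber_params"),
            inherits(smc, "fiber_params"),
            inherits(active, "active_params"),
            rho0_elastin >= 0, rho0_collagen >= 0, rho0_smc >= 0,
            length(collagen_fractions) == 4, all(collagen_fractions >= 0),
            length(collagen_angles) == 4)
  if (abs(sum(collagen_fractions) - 1) > 1e-10) {
    stop("`collagen_fractions` must sum to 1.", call. = FALSE)
  }
  for (nm in c("elastin", "smc", "collagen_circ", "collagen_other")) {
    a <- alloc[[nm]]
    if (is.null(a) || a < 0 || a > 1) {
      stop("`alloc$", nm, "` must lie in [0, 1].", call. = FALSE)
    }
  }
  structure(list(elastin = elastin, collagen = collagen, smc = smc,
                 active = active,
                 rho0_elastin = rho0_elastin, rho0_collagen = rho0_collagen,
                 rho0_smc = rho0_smc,
                 collagen_fractions = collagen_fractions,
                 collagen_angles = collagen_angles, smc_angle = smc_angle,
                 alloc = alloc,
                 smc_drive_includes_active = isTRUE(smc_drive_includes_active)),
            class = "mixture_params")
}

#' Vessel geometry and loading configuration
#'
#' @param inner_radius Loaded in-vivo lumen radius (m).
#' @param wall_thickness Wall thickness in the loaded reference state (m).
#' @param media_fraction Fraction of the wall thickness occupied by the media.
#' @param n_shells_media,n_shells_adventitia Radial discretization per layer.
#' @param n_rings_axial Number of independent axial rings (the long-wavelength
#'   surrogate of an axially varying vessel); 1 gives the single-ring model.
#' @param length Axial model length (m), used to place rings for the spatial
#'   damage weight.
#' @param pressure Luminal pressure (Pa); the default is 80 mmHg.
#' @param lambda0_ez Axial deposition stretch of elastin.
#' @return A list with class `"vessel_config"`.
#' @export
vessel_config <- function(inner_radius = 12.5e-3, wall_thickness = 2.38e-3,
                          media_fraction = 2 / 3, n_shells_media = 6,
                          n_shells_adventitia = 4, n_rings_axial = 1,
                          length = 0.04, pressure = 80 * 133.322,
                          lambda0_ez = 1.3) {
  stopifnot(inner_radius > 0, wall_thickness > 0,
            media_fraction > 0, media_fraction <= 1,
            n_shells_media >= 1, n_shells_adventitia >= 0,
            n_rings_axial >= 1, length > 0, pressure >= 0, lambda0_ez > 0)
  if (media_fraction == 1 && n_shells_adventitia > 0) {
    stop("`media_fraction = 1` requires `n_shells_adventitia = 0`.",
         call. = FALSE)
  }
  structure(list(inner_radius = inner_radius,
                 wall_thickness = wall_thickness,
                 media_fraction = media_fraction,
                 n_shells_media = as.integer(n_shells_media),
                 n_shells_adventitia = as.integer(n_shells_adventitia),
                 n_rings_axial = as.integer(n_rings_axial),
                 length = length, pressure = pressure,
                 lambda0_ez = lambda0_ez),
            class = "vessel_config")
}

#' Numerical settings for the equilibrium solver and time loop
#'
#' @param newton_tol Residual infinity-norm tolerance (Pa) of the radial
#'   Newton solver.
#' @param max_newton_iter Maximal Newton iterations per solve.
#' @param init_tol Displacement tolerance (m) of the homeostatic
#'   initialization fixed point.
#' @param init_max_iter Maximal fixed-point iterations.
#' @param conv_threshold Dimensionless threshold of the dilation convergence
#'   test: the loop may stop when the increase of the normalized average
#'   dilation between successive months falls below this value.
#' @param thickness_norm_T Thickness normalization (m) of the dilation metric.
#' @param dt_days Time step in days (one month).
#' @return A list with class `"solve_settings"`.
#' @export
solve_settings <- function(newton_tol = 1e-4, max_newton_iter = 120,
                           init_tol = 1e-9, init_max_iter = 500,
                           conv_threshold = 0.01, thickness_norm_T = 2.5e-3,
                           dt_days = 30) {
  stopifnot(newton_tol > 0, max_newton_iter >= 1, init_tol > 0,
            init_max_iter >= 1, conv_threshold > 0, thickness_norm_T > 0,
            dt_days > 0)
  structure(list(newton_tol = newton_tol,
                 max_newton_iter = as.integer(max_newton_iter),
                 init_tol = init_tol,
                 init_max_iter = as.integer(init_max_iter),
                 conv_threshold = conv_threshold,
                 thickness_norm_T = thickness_norm_T, dt_days = dt_days),
            class = "solve_settings")
}

#' Sensitivity sweep grid
#'
#' @param t_dam_values Damage times (days).
#' @param k_sigma_values Collagen production gains (dimensionless).
#' @param lambda_max_values Active stretches at maximal active stress.
#' @return A list with class `"sweep_grid"`.
#' @export
sweep_grid <- function(t_dam_values = c(20, 40, 80),
                       k_sigma_values = c(0.05, 0.15, 0.30),
                       lambda_max_values = c(1, 1.1, 1.4)) {
  stopifnot(length(t_dam_values) >= 1, all(t_dam_values > 0),
            length(k_sigma_values) >= 1, all(k_sigma_values >= 0),
            length(lambda_max_values) >= 1, all(lambda_max_values > 0))
  structure(list(t_dam_values = t_dam_values,
                 k_sigma_values = k_sigma_values,
                 lambda_max_values = lambda_max_values),
            class = "sweep_grid")
}

# tension/compression switch on the squared elastic fiber stretch
fiber_k <- function(I4, p) {
  tension <- I4 >= 1
  list(k1 = ifelse(tension, p$k1_t, p$k1_c),
       k2 = ifelse(tension, p$k2_t, p$k2_c))
}
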