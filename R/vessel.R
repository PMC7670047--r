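#' Build a two-layer thick-walled cylinder model
#'
#' Discretizes the wall into radial shells assigned to media and adventitia
#' and allocates the constituent masses layer-wise: 97% of total elastin and
#' 100% of total SMC to the media, 15% of the axial and diagonal collagen to
#' the media, all circumferential collagen to the adventitia (fractions
#' configurable through `params$alloc`). Layer densities are normalized so
#' the volume-integrated mass of each constituent matches the whole-wall
#' totals.
#'
#' @param cfg A [vessel_config()] object.
#' @param params A [mixture_params()] object.
#' @return A list with class `"gr_vessel"`; run [init_homeostatic()] before
#'   simulating.
#' @export
build_two_layer_cylinder <- function(cfg, params) {
  n_m <- cfg$n_shells_media
  n_a <- cfg$n_shells_adventitia
  h <- cfg$wall_thickness
  R_in <- cfg$inner_radius
  R_mid_lay <- R_in + cfg$media_fraction * h
  R_faces <- c(seq(R_in, R_mid_lay, length.out = n_m + 1),
               if (n_a > 0) seq(R_mid_lay, R_in + h,
                                length.out = n_a + 1)[-1])
  layer <- c(rep("media", n_m), rep("adventitia", n_a))
  n <- n_m + n_a
  # reference shell volumes per unit length
  V <- R_faces[-1]^2 - R_faces[-(n + 1)]^2
  V_tot <- sum(V)
  V_med <- sum(V[layer == "media"])
  V_adv <- V_tot - V_med
  is_circ <- abs(params$collagen_angles) < 1e-9
  alloc_c <- ifelse(is_circ, params$alloc$collagen_circ,
                    params$alloc$collagen_other)
  layer_density <- function(total, frac_media, lay) {
    if (lay == "media") {
      total * frac_media * V_tot / V_med
    } else if (V_adv > 0) {
      total * (1 - frac_media) * V_tot / V_adv
    } else {
      0
    }
  }
  rho_e <- rho_m <- numeric(n)
  rho_c <- matrix(0, 4, n)
  for (k in seq_len(n)) {
    rho_e[k] <- layer_density(params$rho0_elastin, params$alloc$elastin,
                              layer[k])
    rho_m[k] <- layer_density(params$rho0_smc, params$alloc$smc, layer[k])
    for (j in seq_len(4)) {
      rho_c[j, k] <- layer_density(
        params$rho0_collagen * params$collagen_fractions[j],
        alloc_c[j], layer[k])
    }
  }
  if (any(rho_e < 0) || any(rho_c < 0) || any(rho_m < 0)) {
    stop("Layer allocation produced a negative density.", call. = FALSE)
  }
  lz <- params$elastin$lambda0_z
  ring <- list(
    layer = layer,
    rho_e = rho_e, rho_c = rho_c, rho_m = rho_m,
    gh_r = rep(1 / lz, n), gh_t = rep(1, n), gh_z = rep(lz, n),
    lam_r_c = matrix(1 / params$collagen$lambda0, 4, n),
    lam_r_m = rep(1 / params$smc$lambda0, n),
    g_rr = rep(1, n),
    rho_e_init = rho_e,
    rho_tot_init = rho_e + colSums(rho_c) + rho_m,
    sig_h_m = rep(NA_real_, n), sig_h_c = matrix(NA_real_, 4, n),
    s_pre_c = matrix(NA_real_, 4, n), s_pre_m = rep(NA_real_, n)
  )
  z <- if (cfg$n_rings_axial == 1) 0 else {
    seq(-cfg$length / 2, cfg$length / 2, length.out = cfg$n_rings_axial)
  }
  structure(list(cfg = cfg, params = params, R_faces = R_faces,
                 layer = layer, ring0 = ring, ring_z = z,
                 initialized = FALSE, r_hom = NULL),
            class = "gr_vessel")
}

#' @export
print.gr_vessel <- function(x, ...) {
  cat("<gr_vessel> two-layer cylinder\n")
  cat(sprintf("  inner radius %.2f mm, thickness %.2f mm, %d shells (%d media / %d adventitia), %d ring(s)\n",
              x$cfg$inner_radius * 1e3, x$cfg$wall_thickness * 1e3,
              length(x$layer), sum(x$layer == "media"),
              sum(x$layer == "adventitia"), length(x$ring_z)))
  cat(sprintf("  pressure %.0f Pa, homeostatic initialization: %s\n",
              x$cfg$pressure, if (x$initialized) "done" else "pending"))
  invisible(x)
}

# vectorized per-shell mechanics of one ring at nodal radii r_faces:
# kinematics, per-constituent Cauchy stress components in the (r, theta, z)
# frame, and the along-fiber scalar stresses driving G&R
shell_mechanics <- function(ring, r_faces, R_faces, params, lambda_z = 1) {
  n <- length(ring$layer)
  dR <- diff(R_faces)
  dr <- diff(r_faces)
  R_mid <- (R_faces[-1] + R_faces[-(n + 1)]) / 2
  r_mid <- (r_faces[-1] + r_faces[-(n + 1)]) / 2
  lam_rr <- dr / dR
  lam_tt <- r_mid / R_mid
  J <- lam_rr * lam_tt * lambda_z
  pe <- params$elastin
  # elastin (all tensors diagonal in the local frame)
  f1 <- lam_rr * ring$gh_r / ring$g_rr
  f2 <- lam_tt * ring$gh_t
  f3 <- lambda_z * ring$gh_z
  J_el <- f1 * f2 * f3
  J_gr <- ring$g_rr / (ring$gh_r * ring$gh_t * ring$gh_z)
  coef <- ring$rho_e / J * pe$mu_e * J_el^(-2 / 3)
  B1 <- f1^2; B2 <- f2^2; B3 <- f3^2
  mB <- (B1 + B2 + B3) / 3
  vol <- ring$rho_e * pe$kappa * (J_el - 1) / J_gr
  srr <- coef * (B1 - mB) + vol
  stt <- coef * (B2 - mB) + vol
  szz <- coef * (B3 - mB) + vol
  stt_e <- stt
  # collagen families
  pc <- params$collagen
  stt_c <- szz_c <- fib_c <- lam_el_c <- matrix(0, 4, n)
  for (j in seq_len(4)) {
    c2 <- cos(params$collagen_angles[j])^2
    s2 <- sin(params$collagen_angles[j])^2
    lamf <- sqrt(lam_tt^2 * c2 + lambda_z^2 * s2)
    lam_el <- lamf / ring$lam_r_c[j, ]
    I4 <- lam_el^2
    k <- fiber_k(I4, pc)
    x <- I4 - 1
    s_mass <- 2 * k$k1 * x * exp(k$k2 * x^2)
    cf <- ring$rho_c[j, ] / J * s_mass / ring$lam_r_c[j, ]^2
    stt_c[j, ] <- cf * lam_tt^2 * c2
    szz_c[j, ] <- cf * lambda_z^2 * s2
    # specific (per-unit-mass) fiber stress: the stress of the extant
    # fibers themselves, independent of how much mass is present
    fib_c[j, ] <- s_mass * I4
    lam_el_c[j, ] <- lam_el
    stt <- stt + stt_c[j, ]
    szz <- szz + szz_c[j, ]
  }
  # SMC passive (circumferential unless configured otherwise)
  pm <- params$smc
  c2m <- cos(params$smc_angle)^2
  s2m <- sin(params$smc_angle)^2
  lam_m <- sqrt(lam_tt^2 * c2m + lambda_z^2 * s2m)
  lam_el_m <- lam_m / ring$lam_r_m
  km <- fiber_k(lam_el_m^2, pm)
  xm <- lam_el_m^2 - 1
  sm_mass <- 2 * km$k1 * xm * exp(km$k2 * xm^2)
  cfm <- ring$rho_m / J * sm_mass / ring$lam_r_m^2
  stt_mp <- cfm * lam_tt^2 * c2m
  szz_mp <- cfm * lambda_z^2 * s2m
  fib_mp <- sm_mass * lam_el_m^2
  # SMC active: stretch tracks the total deformation
  f_act <- active_stress_factor(lam_m / pm$lambda0, params$active)
  s_act <- ring$rho_m / J / ring$rho_tot_init *
    params$active$sigma_act_max * f_act
  fib_act <- params$active$sigma_act_max * f_act / ring$rho_tot_init
  stt_act <- s_act * lam_tt^2 * c2m / lam_m^2
  szz_act <- s_act * lambda_z^2 * s2m / lam_m^2
  stt <- stt + stt_mp + stt_act
  szz <- szz + szz_mp + szz_act
  list(r_mid = r_mid, R_mid = R_mid, lam_rr = lam_rr, lam_tt = lam_tt,
       J = J, J_el = J_el,
       srr = srr, stt = stt, szz = szz, stt_e = stt_e,
       stt_c = stt_c, fib_c = fib_c, lam_el_c = lam_el_c,
       stt_mp = stt_mp, stt_act = stt_act,
       fib_mp = fib_mp, fib_act = fib_act, lam_m = lam_m,
       lam_el_m = lam_el_m, f_act = f_act)
}

#' Discrete radial equilibrium residual of a ring
#'
#' Reduction of linear momentum balance to the axisymmetric radial ODE
#' `d sigma_rr / dr = (sigma_tt - sigma_rr) / r` with traction conditions
#' `sigma_rr = -P` at the lumen and `0` at the outer surface. The ODE is
#' marched across shells by the midpoint rule; the residual asks each
#' shell's constitutive radial stress to equal the marched face average,
#' plus the outer traction condition.
#'
#' @param vessel A [build_two_layer_cylinder()] model.
#' @param r_faces Deformed nodal radii (m), strictly increasing.
#' @param pressure Luminal pressure (Pa).
#' @param ring Optional ring state (defaults to the vessel's).
#' @return Residual vector (Pa) of length `n_shells + 1`.
#' @export
radial_equilibrium_residual <- function(vessel, r_faces,
                                        pressure = vessel$cfg$pressure,
                                        ring = vessel$ring0) {
  if (any(diff(r_faces) <= 0)) {
    stop("Shell inversion: deformed radii must increase outward.",
         call. = FALSE)
  }
  ring_residual(ring, r_faces, vessel$R_faces, pressure, vessel$params)
}

ring_residual <- function(ring, r_faces, R_faces, pressure, params) {
  n <- length(ring$layer)
  mech <- shell_mechanics(ring, r_faces, R_faces, params)
  dT <- (mech$stt - mech$srr) / mech$r_mid * diff(r_faces)
  p_face <- -pressure + c(0, cumsum(dT))
  out <- c(mech$srr - (p_face[-(n + 1)] + p_face[-1]) / 2, p_face[n + 1])
  attr(out, "stress_scale") <- max(abs(mech$stt), pressure)
  out
}

# Newton solve of the radial equilibrium of one ring (finite-difference
# Jacobian, backtracking line search, shell-inversion guard)
solve_ring <- function(ring, r_guess, R_faces, pressure, params, settings) {
  r <- r_guess
  n1 <- length(r)
  res <- ring_residual(ring, r, R_faces, pressure, params)
  best <- max(abs(res))
  # absolute tolerance, relaxed relative to the stress magnitude when the
  # wall is driven far from its physiological range
  tol <- max(settings$newton_tol,
             1e-9 * attr(res, "stress_scale"))
  # a stalled search still counts as converged at the ppm level of the
  # local stress magnitude (finite-difference tangent accuracy limit)
  stall_tol <- function() 1e-5 * attr(res, "stress_scale")
  restarts <- 3
  for (it in seq_len(settings$max_newton_iter)) {
    if (best < tol) {
      return(list(r = r, converged = TRUE, residual = best, iters = it - 1))
    }
    h <- 1e-9
    Jm <- matrix(0, n1, n1)
    for (j in seq_len(n1)) {
      rp <- r
      rp[j] <- rp[j] + h
      rm <- r
      rm[j] <- rm[j] - h
      Jm[, j] <- (ring_residual(ring, rp, R_faces, pressure, params) -
                    ring_residual(ring, rm, R_faces, pressure, params)) /
        (2 * h)
    }
    delta <- tryCatch(solve(Jm, -res), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) {
      return(list(r = r, converged = best < stall_tol(), residual = best,
                  iters = it))
    }
    # cap the update at a fraction of the geometry scale
    cap <- max(0.2 * (r[n1] - r[1]), 0.05 * r[1])
    if (max(abs(delta)) > cap) delta <- delta * cap / max(abs(delta))
    # backtracking on the 2-norm (smoother than the max-norm near curved
    # residual valleys); convergence itself is still tested in max-norm
    nrm2 <- sqrt(sum(res^2))
    alpha <- 1
    repeat {
      r_try <- r + alpha * delta
      ok <- all(diff(r_try) > 0) && all(r_try > 0)
      if (ok) {
        res_try <- tryCatch(
          ring_residual(ring, r_try, R_faces, pressure, params),
          error = function(e) NULL)
        ok <- !is.null(res_try) && all(is.finite(res_try)) &&
          sqrt(sum(res_try^2)) < (1 - 1e-4 * alpha) * nrm2
      }
      if (ok || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    if (!ok) {
      if (best < stall_tol()) {
        return(list(r = r, converged = TRUE, residual = best, iters = it))
      }
      # line search cycling: restart from a slightly inflated state (the
      # soft membrane mode), deterministic
      if (restarts > 0) {
        restarts <- restarts - 1
        r <- r * (1 + 1e-8)
        res <- ring_residual(ring, r, R_faces, pressure, params)
        best <- max(abs(res))
        next
      }
      return(list(r = r, converged = FALSE, residual = best, iters = it))
    }
    r <- r_try
    res <- res_try
    best <- max(abs(res_try))
  }
  list(r = r, converged = best < stall_tol(), residual = best,
       iters = settings$max_newton_iter)
}

# Levenberg-Marquardt fallback for states where damped Newton crawls along
# the curved near-incompressibility valley (thin walls, extreme states)
solve_ring_lm <- function(ring, r_guess, R_faces, pressure, params,
                          settings) {
  n1 <- length(r_guess)
  scale <- max(pressure, 1)
  fn <- function(x) {
    if (any(!is.finite(x)) || any(x <= 0) || any(diff(x) <= 0)) {
      return(rep(1e8, n1))
    }
    out <- tryCatch(
      ring_residual(ring, x, R_faces, pressure, params) / scale,
      error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out))) {
      return(rep(1e8, n1))
    }
    as.numeric(out)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = r_guess, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 150, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(r = r_guess, converged = FALSE, residual = Inf, iters = 0))
  }
  r <- fit$par
  res <- tryCatch(ring_residual(ring, r, R_faces, pressure, params),
                  error = function(e) NULL)
  if (is.null(res)) {
    return(list(r = r_guess, converged = FALSE, residual = Inf, iters = 0))
  }
  best <- max(abs(res))
  tol <- max(settings$newton_tol, 1e-5 * attr(res, "stress_scale"))
  list(r = r, converged = best < tol, residual = best, iters = fit$niter)
}

# Newton with pressure continuation: if the direct solve fails, approach
# the target pressure from `p_hint` (a pressure at which `r_guess` is close
# to equilibrium), bisecting the load path
solve_ring_cont <- function(ring, r_guess, R_faces, pressure, params,
                            settings, p_hint = pressure, depth = 0) {
  sol <- solve_ring(ring, r_guess, R_faces, pressure, params, settings)
  if (!sol$converged) {
    lm <- solve_ring_lm(ring, sol$r, R_faces, pressure, params, settings)
    if (lm$converged) {
      return(lm)
    }
    if (lm$residual < sol$residual) sol <- lm
  }
  if (sol$converged || depth >= 10 ||
      abs(pressure - p_hint) < 1e-9 * max(pressure, p_hint, 1)) {
    return(sol)
  }
  p_mid <- (pressure + p_hint) / 2
  mid <- solve_ring_cont(ring, r_guess, R_faces, p_mid, params, settings,
                         p_hint, depth + 1)
  if (!mid$converged) {
    return(mid)
  }
  solve_ring_cont(ring, mid$r, R_faces, pressure, params, settings,
                  p_mid, depth + 1)
}

#' Solve radial equilibrium of the vessel
#'
#' Newton iterations with a numerical tangent until the residual
#' infinity-norm falls below `settings$newton_tol`.
#'
#' @param vessel A [build_two_layer_cylinder()] model.
#' @param pressure Luminal pressure (Pa).
#' @param settings A [solve_settings()] object.
#' @param r_guess Starting nodal radii (default: the reference radii, or the
#'   homeostatic solution if initialized).
#' @param ring Optional ring state override.
#' @return Deformed nodal radii (m).
#' @export
solve_equilibrium <- function(vessel, pressure = vessel$cfg$pressure,
                              settings = solve_settings(),
                              r_guess = NULL, ring = vessel$ring0) {
  if (is.null(r_guess)) {
    r_guess <- if (!is.null(vessel$r_hom)) vessel$r_hom else vessel$R_faces
  }
  p_hint <- if (isTRUE(vessel$initialized)) vessel$cfg$pressure else 0
  out <- solve_ring_cont(ring, r_guess, vessel$R_faces, pressure,
                         vessel$params, settings, p_hint)
  if (!out$converged) {
    stop(sprintf("Equilibrium solve did not converge (|res| = %.3g Pa).",
                 out$residual), call. = FALSE)
  }
  out$r
}

#' Homeostatic initialization of the loaded reference state
#'
#' Iteratively adjusts the per-shell elastin deposition tensor (damped
#' multiplicative fixed point on its circumferential and radial components)
#' until solving equilibrium at the luminal pressure returns the reference
#' geometry to within `settings$init_tol`. The converged state defines
#' homeostasis: target fiber stresses and deposition pre-stresses are
#' recorded from it.
#'
#' @param vessel A freshly built [build_two_layer_cylinder()] model.
#' @param settings A [solve_settings()] object.
#' @param damping Fixed-point damping exponent in (0, 1].
#' @return The initialized `gr_vessel`.
#' @export
init_homeostatic <- function(vessel, settings = solve_settings(),
                             damping = 1) {
  ring <- vessel$ring0
  R <- vessel$R_faces
  params <- vessel$params
  P <- vessel$cfg$pressure
  n <- length(ring$layer)
  R_mid <- (R[-1] + R[-(n + 1)]) / 2
  fixed_point <- function(ring, P_stage, tol, max_iter) {
    r <- R
    disp_prev <- Inf
    eta <- damping
    for (it in seq_len(max_iter)) {
      sol <- solve_ring_cont(ring, r, R, P_stage, params, settings,
                             p_hint = 0)
      if (!sol$converged) {
        stop(sprintf(
          "Homeostatic initialization: equilibrium solve failed at iteration %d (|res| = %.3g Pa).",
          it, sol$residual), call. = FALSE)
      }
      r <- sol$r
      disp <- max(abs(r - R))
      if (disp < tol) {
        return(list(ring = ring, r = r))
      }
      if (disp > disp_prev) eta <- max(eta / 2, 0.1)
      disp_prev <- disp
      r_mid <- (r[-1] + r[-(n + 1)]) / 2
      ring$gh_t <- ring$gh_t * (r_mid / R_mid)^eta
      ring$gh_r <- ring$gh_r * (diff(r) / diff(R))^eta
      r <- R
    }
    stop(sprintf(
      "Homeostatic initialization did not converge: displacement %.3g m after %d iterations.",
      disp, max_iter), call. = FALSE)
  }
  out <- tryCatch(fixed_point(ring, P, settings$init_tol,
                              settings$init_max_iter),
                  error = function(e) NULL)
  if (is.null(out)) {
    # a stress-free start may have no equilibrium at full pressure (finite
    # membrane capacity); bootstrap the deposition prestretch by ramping
    # the pressure and re-absorbing at every stage
    for (P_stage in P * c(1 / 32, 1 / 16, 1 / 8, 1 / 4, 1 / 2)) {
      out <- fixed_point(ring, P_stage, max(settings$init_tol, 1e-8),
                         settings$init_max_iter)
      ring <- out$ring
    }
    out <- fixed_point(ring, P, settings$init_tol, settings$init_max_iter)
  }
  ring <- out$ring
  r <- out$r
  # record homeostatic targets from the converged solved state
  mech <- shell_mechanics(ring, r, R, params)
  ring$sig_h_c <- mech$fib_c
  ring$sig_h_m <- if (params$smc_drive_includes_active) {
    mech$fib_mp + mech$fib_act
  } else {
    mech$fib_mp
  }
  ring$s_pre_c <- matrix(fiber_pk2_per_mass(mech$lam_el_c, params$collagen),
                         4, length(ring$layer))
  ring$s_pre_m <- fiber_pk2_per_mass(mech$lam_el_m, params$smc)
  vessel$ring0 <- ring
  vessel$r_hom <- r
  vessel$initialized <- TRUE
  vessel
}

#' Normalized average dilation metric
#'
#' `u_ave = 100 * sum(|u_i|) / (N_e * T)`: the average element displacement
#' normalized by the wall thickness scale `T`, in percent. The time loop's
#' stop test compares successive values of this metric.
#'
#' @param displacements Per-element displacement norms (m).
#' @param N_e Number of elements.
#' @param T_norm Thickness normalization (m).
#' @return Dimensionless metric.
#' @export
convergence_metric <- function(displacements, N_e = length(displacements),
                               T_norm = 2.5e-3) {
  stopifnot(N_e > 0, T_norm > 0)
  100 * sum(abs(displacements)) / (N_e * T_norm)
}

# vectorized G&R advance of a whole ring (same update as
# step_material_point, applied shell-wise)
step_ring <- function(ring, r_faces, R_faces, t, dt, d, params, weight) {
  mech <- shell_mechanics(ring, r_faces, R_faces, params)
  if (any(!is.finite(mech$stt))) {
    stop("Non-finite stresses in ring; cannot advance state.",
         call. = FALSE)
  }
  drive_m <- if (params$smc_drive_includes_active) {
    mech$fib_mp + mech$fib_act
  } else {
    mech$fib_mp
  }
  media <- ring$layer == "media"
  n <- length(ring$layer)
  rho_dot_c <- matrix(0, 4, n)
  new_lam_r_c <- ring$lam_r_c
  for (j in seq_len(4)) {
    drive <- ifelse(media, drive_m, mech$fib_c[j, ])
    target <- ifelse(media, ring$sig_h_m, ring$sig_h_c[j, ])
    rho_dot_c[j, ] <- collagen_production_rate(drive, target,
                                               ring$rho_c[j, ],
                                               params$collagen)
    act <- ring$rho_c[j, ] > 0
    if (any(act)) {
      rr <- remodeling_rate(mech$lam_el_c[j, act], ring$lam_r_c[j, act],
                            ring$s_pre_c[j, act],
                            rho_dot_c[j, act] / ring$rho_c[j, act],
                            params$collagen)
      new_lam_r_c[j, act] <- ring$lam_r_c[j, act] + dt * rr
    }
  }
  new_lam_r_m <- ring$lam_r_m
  actm <- ring$rho_m > 0
  if (any(actm)) {
    rr_m <- remodeling_rate(mech$lam_el_m[actm], ring$lam_r_m[actm],
                            ring$s_pre_m[actm], 0, params$smc)
    new_lam_r_m[actm] <- ring$lam_r_m[actm] + dt * rr_m
  }
  rho_e_new <- elastin_density_step(t, dt, ring$rho_e, ring$rho_e_init,
                                    params$elastin, d, weight)
  rho_dot_e_eff <- (rho_e_new - ring$rho_e) / dt
  rho0_total <- ring$rho_e + colSums(ring$rho_c) + ring$rho_m
  g_dot <- (rho_dot_e_eff + colSums(rho_dot_c)) / rho0_total * ring$g_rr
  ring$g_rr <- pmax(ring$g_rr + dt * g_dot, 1e-6)
  ring$rho_e <- rho_e_new
  ring$rho_c <- pmax(ring$rho_c + dt * rho_dot_c, 0)
  ring$lam_r_c <- pmax(new_lam_r_c, 1e-3)
  ring$lam_r_m <- pmax(new_lam_r_m, 1e-3)
  ring
}

# advance one ring by dt and re-solve equilibrium; on solver failure the
# G&R step is bisected recursively (the staggered scheme is kept: stresses
# always come from the last solved state)
advance_ring <- function(ring, r, R_faces, t, dt, d, params, weight,
                         pressure, settings, depth = 0) {
  st <- step_ring(ring, r, R_faces, t, dt, d, params, weight)
  # far from homeostasis the G&R rates can exceed the monthly resolution;
  # bound the relative state change per explicit substep
  change <- max(abs(st$lam_r_c / ring$lam_r_c - 1),
                abs(st$lam_r_m / ring$lam_r_m - 1),
                abs(st$g_rr / ring$g_rr - 1),
                abs(st$rho_c - ring$rho_c) / (ring$rho_c + 1))
  sol <- if (change <= 0.25 || depth >= 8) {
    solve_ring_cont(st, r, R_faces, pressure, params, settings)
  } else {
    list(converged = FALSE, residual = Inf)
  }
  if (sol$converged) {
    return(list(state = st, r = sol$r))
  }
  if (depth >= 8) {
    stop(sprintf("equilibrium diverged (|res| = %.3g Pa) despite step bisection",
                 sol$residual), call. = FALSE)
  }
  half1 <- advance_ring(ring, r, R_faces, t, dt / 2, d, params, weight,
                        pressure, settings, depth + 1)
  advance_ring(half1$state, half1$r, R_faces, t + dt / 2, dt / 2, d,
               params, weight, pressure, settings, depth + 1)
}

# per-step scalar summaries of one ring (volume-weighted wall averages)
ring_summary <- function(ring, r_faces, R_faces, params, probe) {
  n <- length(ring$layer)
  mech <- shell_mechanics(ring, r_faces, R_faces, params)
  w <- r_faces[-1]^2 - r_faces[-(n + 1)]^2
  w <- w / sum(w)
  media <- ring$layer == "media"
  wm <- w[media] / sum(w[media])
  stt_smc <- mech$stt_mp + mech$stt_act
  act_mean <- sum(w * mech$stt_act)
  act_mean_media <- sum(wm * mech$stt_act[media])
  smc_mean_media <- sum(wm * stt_smc[media])
  tot_mean <- sum(w * mech$stt)
  share <- w * mech$stt
  adv_share <- if (any(!media)) sum(share[!media]) / sum(share) else 0
  tibble::tibble(
    r_inner = r_faces[1], r_outer = r_faces[n + 1],
    thickness = r_faces[n + 1] - r_faces[1],
    mean_stress_total = tot_mean,
    mean_stress_active = act_mean,
    mean_stress_smc = smc_mean_media,
    R_m = if (smc_mean_media > 0) act_mean_media / smc_mean_media else 0,
    R_t = if (tot_mean > 0) act_mean / tot_mean else 0,
    adv_stress_share = adv_share,
    lambda_m_probe = mech$lam_m[probe],
    lambda_act_probe = mech$lam_m[probe] / params$smc$lambda0,
    stress_active_probe = mech$stt_act[probe],
    f_act_probe = mech$f_act[probe],
    rho_elastin_mean = sum(w * ring$rho_e),
    rho_collagen_mean = sum(w * colSums(ring$rho_c)),
    rho_smc_mean = sum(w * ring$rho_m),
    shells = list(tibble::tibble(
      shell = seq_len(n), layer = ring$layer, r_mid = mech$r_mid,
      lam_tt = mech$lam_tt, srr = mech$srr, stt = mech$stt,
      stt_active = mech$stt_act, stt_smc = stt_smc,
      fib_smc = mech$fib_mp + mech$fib_act,
      lambda_m = mech$lam_m, f_act = mech$f_act,
      rho_e = ring$rho_e, rho_c_total = colSums(ring$rho_c),
      rho_m = ring$rho_m, g_rr = ring$g_rr))
  )
}

#' Run a growth-and-remodeling simulation
#'
#' Monthly staggered time loop: each step solves radial equilibrium, then
#' advances every material point using the stresses of the solved state.
#' Recording covers the damage-center ring in detail plus the lumen radius
#' of every ring. The loop stops at the horizon, or earlier when the
#' increase of the normalized average dilation between successive months
#' falls below `settings$conv_threshold` (checked only once dilation has
#' started, and only if `stop_on_convergence` is set).
#'
#' @param vessel An initialized `gr_vessel` (see [init_homeostatic()]).
#' @param damage A [damage_params()] object.
#' @param horizon_months Number of monthly steps (default 180, 15 years).
#' @param settings A [solve_settings()] object.
#' @param stop_on_convergence Logical; allow early stopping on the dilation
#'   convergence test.
#' @return A tibble with class `"gr_trajectory"`, one row per recorded
#'   month; per-shell detail in the `shells` list-column, run metadata in
#'   attributes.
#' @export
run_simulation <- function(vessel, damage = damage_params(),
                           horizon_months = 180,
                           settings = solve_settings(),
                           stop_on_convergence = TRUE) {
  if (!isTRUE(vessel$initialized)) {
    stop("Run `init_homeostatic()` before simulating.", call. = FALSE)
  }
  cfg <- vessel$cfg
  params <- vessel$params
  R <- vessel$R_faces
  weights <- if (!damage$enabled) {
    rep(0, length(vessel$ring_z))
  } else {
    exp(-((vessel$ring_z - damage$center) / damage$L_dam)^2)
  }
  center <- which.max(weights)
  n_m <- sum(vessel$layer == "media")
  probe <- max(1L, as.integer(ceiling(n_m / 2)))
  rings <- lapply(seq_along(weights), function(i) {
    list(state = vessel$ring0, r = vessel$r_hom)
  })
  dt <- settings$dt_days
  rows <- vector("list", horizon_months + 1)
  r_inner_all <- matrix(NA_real_, horizon_months + 1, length(rings))
  rows[[1]] <- dplyr::bind_cols(
    tibble::tibble(month = 0, u_ave = 0, du_ave = 0),
    ring_summary(rings[[center]]$state, rings[[center]]$r, R, params, probe))
  r_inner_all[1, ] <- vapply(rings, function(rg) rg$r[1], numeric(1))
  u_prev <- 0
  months_run <- 0L
  stopped <- FALSE
  failed <- FALSE
  fail_msg <- NA_character_
  for (n in seq_len(horizon_months)) {
    t_prev <- (n - 1) * dt
    ok <- tryCatch({
      for (i in seq_along(rings)) {
        rings[[i]] <- advance_ring(rings[[i]]$state, rings[[i]]$r, R,
                                   t_prev, dt, damage, params, weights[i],
                                   cfg$pressure, settings)
      }
      TRUE
    }, error = function(e) {
      fail_msg <<- conditionMessage(e)
      FALSE
    })
    if (!ok) {
      failed <- TRUE
      break
    }
    months_run <- n
    disp <- unlist(lapply(rings, function(rg) {
      nn <- length(rg$r)
      abs((rg$r[-1] + rg$r[-nn]) / 2 - (R[-1] + R[-length(R)]) / 2)
    }))
    u_ave <- convergence_metric(disp, length(disp),
                                settings$thickness_norm_T)
    rows[[n + 1]] <- dplyr::bind_cols(
      tibble::tibble(month = n, u_ave = u_ave, du_ave = u_ave - u_prev),
      ring_summary(rings[[center]]$state, rings[[center]]$r, R, params,
                   probe))
    r_inner_all[n + 1, ] <- vapply(rings, function(rg) rg$r[1], numeric(1))
    if (stop_on_convergence && u_ave > settings$conv_threshold &&
        (u_ave - u_prev) < settings$conv_threshold) {
      stopped <- TRUE
      u_prev <- u_ave
      break
    }
    u_prev <- u_ave
  }
  traj <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  traj <- tibble::new_tibble(traj, class = "gr_trajectory",
                             nrow = nrow(traj))
  attr(traj, "cfg") <- cfg
  attr(traj, "params") <- params
  attr(traj, "damage") <- damage
  attr(traj, "settings") <- settings
  attr(traj, "probe_shell") <- probe
  attr(traj, "months_run") <- months_run
  attr(traj, "stopped_early") <- stopped
  attr(traj, "failed") <- failed
  attr(traj, "failure_message") <- fail_msg
  attr(traj, "r_inner_rings") <- r_inner_all[seq_len(months_run + 1), ,
                                             drop = FALSE]
  attr(traj, "final_state") <- rings[[center]]$state
  attr(traj, "final_radii") <- rings[[center]]$r
  traj
}

#' Extract one shell of a vessel as a material point
#'
#' Bridges the vectorized ring representation and the pointwise operations:
#' the returned [material_point()] reproduces the shell's constituent state,
#' so pointwise stress and update functions can be cross-checked against
#' the vectorized solver path.
#'
#' @param vessel A `gr_vessel`.
#' @param shell Shell index.
#' @return A [material_point()].
#' @export
extract_material_point <- function(vessel, shell) {
  ring <- vessel$ring0
  params <- vessel$params
  pt <- material_point(params,
                       layer = ring$layer[shell],
                       rho_e = ring$rho_e[shell],
                       rho_c = ring$rho_c[, shell],
                       rho_m = ring$rho_m[shell])
  pt$gh_e <- c(ring$gh_r[shell], ring$gh_t[shell], ring$gh_z[shell])
  pt$lam_r_c <- ring$lam_r_c[, shell]
  pt$lam_r_m <- ring$lam_r_m[shell]
  pt$g_rr <- ring$g_rr[shell]
  pt$rho_e_init <- ring$rho_e_init[shell]
  pt$rho_tot_init <- ring$rho_tot_init[shell]
  pt$sig_h_m <- ring$sig_h_m[shell]
  pt$sig_h_c <- ring$sig_h_c[, shell]
  pt$s_pre_c <- ring$s_pre_c[, shell]
  pt$s_pre_m <- ring$s_pre_m[shell]
  pt
}
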