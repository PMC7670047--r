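test_that("layer allocation conserves the whole-wall constituent masses", {
  cfg <- vessel_config()
  params <- mixture_params()
  v <- build_two_layer_cylinder(cfg, params)
  n <- length(v$layer)
  V <- v$R_faces[-1]^2 - v$R_faces[-(n + 1)]^2
  wall_mean <- function(x) sum(x * V) / sum(V)
  expect_equal(wall_mean(v$ring0$rho_e), 250, tolerance = 1e-12)
  expect_equal(wall_mean(colSums(v$ring0$rho_c)), 460, tolerance = 1e-12)
  expect_equal(wall_mean(v$ring0$rho_m), 280, tolerance = 1e-12)
  # adventitia carries no smooth muscle, media no circumferential collagen
  adv <- v$layer == "adventitia"
  expect_true(all(v$ring0$rho_m[adv] == 0))
  expect_true(all(v$ring0$rho_c[1, !adv] == 0))
  # single-layer wall keeps the media shares only
  v1 <- build_two_layer_cylinder(
    vessel_config(media_fraction = 1, n_shells_adventitia = 0), params)
  expect_equal(unique(v1$ring0$rho_e), 0.97 * 250, tolerance = 1e-12)
  expect_equal(unique(v1$ring0$rho_m), 280, tolerance = 1e-12)
})

test_that("homeostatic initialization returns the reference geometry under load", {
  v <- init_vessel(1.4)
  r <- solve_equilibrium(v)
  expect_lt(max(abs(r - v$R_faces)), 1e-9)
  # every collagen family sits at its deposition stretch: I4 = 1.21
  mech <- vesselgr:::shell_mechanics(v$ring0, v$r_hom, v$R_faces, v$params)
  expect_equal(as.vector(mech$lam_el_c^2), rep(1.21, 40), tolerance = 1e-6)
  expect_true(all(v$ring0$sig_h_m[v$layer == "media"] > 0))
  expect_true(all(v$ring0$sig_h_c > 0))
})

test_that("the equilibrium residual vanishes for a stress-free unloaded tube", {
  cfg <- make_preset("thinwall_verification")
  p <- cfg$materials
  p$elastin <- elastin_params(lambda0_z = 1, T_e_days = Inf)
  v <- build_two_layer_cylinder(cfg$vessel, p)
  v$ring0$gh_r <- rep(1, 10); v$ring0$gh_t <- rep(1, 10)
  v$ring0$gh_z <- rep(1, 10)
  res <- radial_equilibrium_residual(v, v$R_faces, pressure = 0)
  expect_equal(max(abs(res)), 0, tolerance = 1e-12)
  expect_error(radial_equilibrium_residual(v, rev(v$R_faces)), "inversion")
})

test_that("the discretized tube matches a dense shooting integration of the equilibrium ODE", {
  skip_if_not_installed("deSolve")
  # unit-deposition elastin tube inflated from its stress-free state
  cfg <- vessel_config(inner_radius = 10e-3, wall_thickness = 1e-3,
                       media_fraction = 1, n_shells_media = 60,
                       n_shells_adventitia = 0, pressure = 1000,
                       lambda0_ez = 1)
  params <- mixture_params(
    elastin = elastin_params(lambda0_z = 1, T_e_days = Inf),
    rho0_collagen = 0, rho0_smc = 0,
    active = active_params(sigma_act_max = 0))
  v <- build_two_layer_cylinder(cfg, params)
  n <- 60
  v$ring0$gh_r <- rep(1, n); v$ring0$gh_t <- rep(1, n)
  v$ring0$gh_z <- rep(1, n)
  r <- solve_equilibrium(v, r_guess = v$R_faces * 1.05)

  # independent oracle: integrate d(sigma_rr)/dR with the radial stretch
  # recovered pointwise by a 1-D root find on the constitutive law
  rho_e <- v$ring0$rho_e[1]
  pe <- params$elastin
  sig <- function(lam_r, lam_t) {
    Fel <- diag(c(lam_r, lam_t, 1))
    elastin_cauchy_stress(Fel, rho_e, 1, pe)
  }
  rhs <- function(R, y, parms) {
    lam_t <- y[1] / R
    f <- function(lr) sig(lr, lam_t)[1, 1] - y[2]
    lam_r <- stats::uniroot(f, c(1e-3, 20), tol = 1e-14)$root
    s <- sig(lam_r, lam_t)
    list(c(lam_r, (s[2, 2] - s[1, 1]) / y[1] * lam_r))
  }
  shoot <- function(r_in) {
    out <- deSolve::lsoda(c(r_in, -cfg$pressure), v$R_faces, rhs,
                          rtol = 1e-10, atol = 1e-12)
    out
  }
  outer_sig <- function(r_in) tail(shoot(r_in)[, 3], 1)
  r_in_oracle <- stats::uniroot(outer_sig, c(r[1] * 0.99, r[1] * 1.01),
                                tol = 1e-12)$root
  sol <- shoot(r_in_oracle)
  expect_lt(max(abs(r - sol[, 2]) / sol[, 2]), 1e-4)
})

test_that("pressurization is monotone and elastin becomes incompressible as kappa grows", {
  v <- init_vessel(1.4)
  s <- solve_settings()
  r1 <- solve_equilibrium(v, pressure = v$cfg$pressure, settings = s)
  r2 <- solve_equilibrium(v, pressure = 1.5 * v$cfg$pressure, settings = s)
  expect_gt(r2[1], r1[1])
  # unloading recoils inward ("zero pressure state")
  r0 <- solve_equilibrium(v, pressure = 0, settings = s)
  expect_lt(r0[1], r1[1])

  jel_dev <- vapply(c(10, 100, 1000), function(ratio) {
    cfg <- vessel_config(inner_radius = 10e-3, wall_thickness = 1e-3,
                         media_fraction = 1, n_shells_media = 8,
                         n_shells_adventitia = 0, pressure = 1000,
                         lambda0_ez = 1)
    params <- mixture_params(
      elastin = elastin_params(mu_e = 82, kappa = ratio * 82,
                               lambda0_z = 1, T_e_days = Inf),
      rho0_collagen = 0, rho0_smc = 0,
      active = active_params(sigma_act_max = 0))
    vv <- build_two_layer_cylinder(cfg, params)
    n <- 8
    vv$ring0$gh_r <- rep(1, n); vv$ring0$gh_t <- rep(1, n)
    vv$ring0$gh_z <- rep(1, n)
    r <- solve_equilibrium(vv, r_guess = vv$R_faces * 1.05)
    mech <- vesselgr:::shell_mechanics(vv$ring0, r, vv$R_faces, params)
    max(abs(mech$J_el - 1))
  }, numeric(1))
  expect_true(all(diff(jel_dev) < 0))
})

test_that("the dilation metric is the normalized displacement average", {
  expect_equal(convergence_metric(rep(0, 10), 10, 2.5e-3), 0)
  expect_equal(convergence_metric(rep(2.5e-3 / 100, 7), 7, 2.5e-3), 1)
  set.seed(3)
  u <- runif(12)
  expect_equal(convergence_metric(u, 12, 2.5e-3),
               convergence_metric(sample(u), 12, 2.5e-3))
})

test_that("trajectories are deterministic and respect basic structure", {
  v <- init_vessel(1.0)
  d <- damage_params(D_max = 0.5, t_dam = 40)
  t1 <- run_simulation(v, d, horizon_months = 6, stop_on_convergence = FALSE)
  t2 <- run_simulation(v, d, horizon_months = 6, stop_on_convergence = FALSE)
  expect_identical(t1$r_inner, t2$r_inner)
  expect_identical(t1$R_t, t2$R_t)
  # radii increase outward in every recorded step; growth stays invertible
  for (k in seq_len(nrow(t1))) {
    expect_true(all(diff(t1$shells[[k]]$r_mid) > 0))
    expect_true(all(t1$shells[[k]]$g_rr > 0))
  }
  # elastin decays monotonically under damage
  expect_true(all(diff(t1$rho_elastin_mean) < 0))
})

test_that("halving the time step changes the trajectory at first order", {
  v <- init_vessel(1.4)
  d <- damage_params(D_max = 0.5, t_dam = 40)
  final_r <- vapply(c(30, 15, 7.5), function(dt) {
    s <- solve_settings(dt_days = dt)
    tr <- run_simulation(v, d, horizon_months = round(12 * 30 / dt),
                         settings = s, stop_on_convergence = FALSE)
    tr$r_inner[nrow(tr)]
  }, numeric(1))
  e1 <- abs(final_r[1] - final_r[3])
  e2 <- abs(final_r[2] - final_r[3])
  expect_gt(e1 / e2, 1.5)   # consistent with O(dt) convergence
  expect_lt(e1 / e2, 6)
})

test_that("fast vectorized shell stresses equal the tensorial point stresses", {
  v <- init_vessel(1.4)
  n <- length(v$layer)
  set.seed(11)
  r <- v$r_hom * 1.03 + cumsum(runif(n + 1, 0, 2e-5))
  ring <- v$ring0
  ring$lam_r_c <- ring$lam_r_c * exp(matrix(runif(4 * n, -0.03, 0.03), 4, n))
  ring$lam_r_m <- ring$lam_r_m * exp(runif(n, -0.03, 0.03))
  ring$g_rr <- exp(runif(n, -0.03, 0.03))
  mech <- vesselgr:::shell_mechanics(ring, r, v$R_faces, v$params)
  R_mid <- (v$R_faces[-1] + v$R_faces[-(n + 1)]) / 2
  vv <- v
  vv$ring0 <- ring
  for (shell in c(2, 6, 9)) {
    pt <- extract_material_point(vv, shell)
    F <- diag(c(diff(r)[shell] / diff(v$R_faces)[shell],
                ((r[-1] + r[-(n + 1)]) / 2)[shell] / R_mid[shell], 1))
    sig <- mixture_cauchy_stress(pt, F, v$params)
    expect_equal(mech$srr[shell], sig[1, 1], tolerance = 1e-10)
    expect_equal(mech$stt[shell], sig[2, 2], tolerance = 1e-10)
    expect_equal(mech$szz[shell], sig[3, 3], tolerance = 1e-10)
  }
})
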