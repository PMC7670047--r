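test_that("elastin degradation combines slow turnover and the damage pulse", {
  pe <- elastin_params()   # T_e = 101 years = 36865 days
  d_on <- damage_params(D_max = 0.5, t_dam = 40)
  d_off <- damage_params(D_max = 0, enabled = FALSE)
  expect_equal(elastin_degradation_rate(0, 250, 250, pe, d_off), -250 / 36865)
  expect_equal(elastin_degradation_rate(0, 250, 250, pe, d_on, 1),
               -250 / 36865 - 3.125)
  expect_equal(elastin_degradation_rate(0, 250, 250, pe, d_on, 0),
               -250 / 36865)
  # long after the pulse only background turnover remains
  expect_equal(elastin_degradation_rate(100 * 40, 200, 250, pe, d_on, 1),
               -200 / 36865, tolerance = 1e-12)
  expect_true(all(elastin_degradation_rate(seq(0, 400, 25), 250, 250,
                                           pe, d_on, 1) <= 0))
})

test_that("the integrated damage pulse removes exactly D_max of the initial elastin", {
  pe <- elastin_params(T_e_days = Inf)   # isolate the damage term
  d <- damage_params(D_max = 0.5, t_dam = 20)
  rho <- 250
  t <- 0
  for (i in 1:40) {                      # 40 months >> t_dam
    rho <- elastin_density_step(t, 30, rho, 250, pe, d, 1)
    t <- t + 30
  }
  expect_equal(rho, 250 * (1 - 0.5), tolerance = 1e-10)
  # and the closed form matches the exact solution at finite T_e
  pe2 <- elastin_params(T_e_days = 1000)
  a <- 1 / 1000; b <- 1 / 20
  exact <- function(t) {
    250 * exp(-a * t) - 0.5 * 250 * b / (b - a) * (exp(-a * t) - exp(-b * t))
  }
  rho <- 250; t <- 0
  for (i in 1:12) {
    rho <- elastin_density_step(t, 30, rho, 250, pe2, d, 1)
    t <- t + 30
  }
  expect_equal(rho, exact(360), tolerance = 1e-9)
})

test_that("collagen production follows the stress deviation from homeostasis", {
  p <- fiber_params(k_sigma = 0.05, T_days = 101)
  expect_equal(collagen_production_rate(100, 100, 460, p), 0)
  expect_equal(collagen_production_rate(110, 100, 460, p),
               460 * (0.05 / 101) * 0.1, tolerance = 1e-12)
  expect_lt(collagen_production_rate(90, 100, 460, p), 0)
  expect_error(collagen_production_rate(100, 0, 460, p), "positive")
})

test_that("remodeling is stationary at the deposition pre-stress and relaxes overstress", {
  p <- fiber_params(k1_t = 105, k2_t = 0.13, lambda0 = 1.1, T_days = 101)
  s_pre <- vesselgr:::fiber_pk2_per_mass(1.1, p)
  expect_identical(remodeling_rate(1.1, 1 / 1.1, s_pre, 0, p), 0)
  expect_gt(remodeling_rate(1.2, 1 / 1.1, s_pre, 0, p), 0)
  expect_lt(remodeling_rate(1.05, 1 / 1.1, s_pre, 0, p), 0)
})

test_that("fiber stress relaxes toward the pre-stress exponentially at rate 1/T", {
  # integrate the remodeling ODE at frozen total stretch; the overstress
  # must decay like exp(-t/T) (the closed-form behavior of the law)
  p <- fiber_params(k1_t = 105, k2_t = 0.13, lambda0 = 1.1, T_days = 101)
  lam_fib <- 1.25          # frozen total fiber stretch
  lam_r <- 1 / 1.1         # deposition state: lam_el = 1.375 (overstretch)
  s_pre <- vesselgr:::fiber_pk2_per_mass(1.21 / 1.1, p)
  dt <- 0.05
  t_end <- 101
  s0 <- vesselgr:::fiber_pk2_per_mass(lam_fib / lam_r, p) - s_pre
  lam_hist <- lam_r
  for (t in seq(0, t_end - dt, by = dt)) {
    lam_r <- lam_r + dt * remodeling_rate(lam_fib / lam_r, lam_r, s_pre, 0, p)
  }
  s_end <- vesselgr:::fiber_pk2_per_mass(lam_fib / lam_r, p) - s_pre
  expect_equal(s_end / s0, exp(-1), tolerance = 2e-3)
})

test_that("growth is rank-one radial and tracks the relative mass change", {
  expect_equal(growth_rate(c(0, 0, 0), 990, diag(3)), matrix(0, 3, 3))
  Fg <- diag(c(1.3, 1, 1))
  G <- growth_rate(c(1, 2, 0.5), 990, Fg)
  expect_equal(G[-1, ], matrix(0, 2, 3))
  expect_equal(G[1, -1], c(0, 0))
  # ODE oracle: at constant rho_dot/rho, det F_g tracks rho(t)/rho(0)
  rho0 <- 990; rho <- rho0
  g <- 1
  c_rate <- 2e-3
  for (i in 1:500) {          # dt = 1 day
    rdot <- c_rate * rho
    g <- g + growth_rate(c(rdot, 0, 0), rho, diag(c(g, 1, 1)))[1, 1]
    rho <- rho + rdot
  }
  expect_equal(g, rho / rho0, tolerance = 1e-3)
})

test_that("a homeostatic material point is a fixed point of the monthly update", {
  params <- mixture_params()
  pt <- material_point(params, "media")
  d_off <- damage_params(D_max = 0, enabled = FALSE)
  p_inf <- params
  p_inf$elastin <- elastin_params(T_e_days = Inf)
  stepped <- step_material_point(pt, diag(3), 0, 30, d_off, p_inf)
  for (f in c("rho_e", "rho_c", "rho_m", "lam_r_c", "lam_r_m", "g_rr")) {
    expect_equal(stepped[[f]], pt[[f]], tolerance = 1e-12)
  }
})

test_that("collagen density bookkeeping is exactly forward Euler", {
  params <- mixture_params()
  pt <- material_point(params, "media")
  F <- diag(c(0.98, 1.05, 1))      # out of homeostasis
  st <- constituent_stresses(pt, F, params)
  expected <- pt$rho_c + 30 * vapply(1:4, function(j) {
    collagen_production_rate(st$fiber_stress_m_total, pt$sig_h_m,
                             pt$rho_c[j], params$collagen)
  }, numeric(1))
  stepped <- step_material_point(pt, F, 0, 30,
                                 damage_params(enabled = FALSE), params)
  expect_equal(stepped$rho_c, expected, tolerance = 1e-14)
})

test_that("pointwise and vectorized ring updates agree shell by shell", {
  v <- init_vessel(1.4)
  params <- v$params
  d <- damage_params(D_max = 0.5, t_dam = 40)
  # push the ring out of equilibrium, then compare one update step
  r <- v$r_hom * 1.02
  stepped_ring <- vesselgr:::step_ring(v$ring0, r, v$R_faces, 60, 30, d,
                                       params, 1)
  n <- length(v$layer)
  R_mid <- (v$R_faces[-1] + v$R_faces[-(n + 1)]) / 2
  for (shell in c(1, 4, 7, 10)) {
    pt <- extract_material_point(v, shell)
    F <- diag(c(diff(r)[shell] / diff(v$R_faces)[shell],
                ((r[-1] + r[-(n + 1)]) / 2)[shell] / R_mid[shell], 1))
    spt <- step_material_point(pt, F, 60, 30, d, params, 1)
    expect_equal(spt$rho_e, stepped_ring$rho_e[shell], tolerance = 1e-10)
    expect_equal(spt$rho_c, stepped_ring$rho_c[, shell], tolerance = 1e-10)
    expect_equal(spt$lam_r_c, stepped_ring$lam_r_c[, shell],
                 tolerance = 1e-10)
    expect_equal(spt$lam_r_m, stepped_ring$lam_r_m[shell],
                 tolerance = 1e-10)
    expect_equal(spt$g_rr, stepped_ring$g_rr[shell], tolerance = 1e-10)
  }
})
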