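test_that("deposition stretch tensors are volume preserving with the printed structure", {
  expect_equal(deposition_stretch_elastin(1, 1), diag(3))
  G <- deposition_stretch_elastin(1.2, 1.3)
  expect_equal(diag(G), c(0.641025641025641, 1.2, 1.3))
  expect_equal(det(G), 1)
  for (lt in c(0.8, 1.1, 1.7)) {
    for (lz in c(0.9, 1.3)) {
      expect_equal(det(deposition_stretch_elastin(lt, lz)), 1)
    }
  }
  expect_error(deposition_stretch_elastin(-1, 1.3), "positive")

  expect_equal(deposition_stretch_fiber(1, c(0, 1, 0)), diag(3))
  Gf <- deposition_stretch_fiber(1.1, c(0, 1, 0))
  expect_equal(diag(Gf), c(0.953462589245592, 1.1, 0.953462589245592))
  expect_equal(det(Gf), 1, tolerance = 1e-12)
  a <- c(0, 1, 1) / sqrt(2)
  for (l0 in c(0.7, 1.1, 2)) {
    expect_equal(det(deposition_stretch_fiber(l0, a)), 1, tolerance = 1e-12)
  }
  expect_error(deposition_stretch_fiber(1.1, c(0, 0, 0)), "nonzero")
})

test_that("elastic deformation honors the multiplicative split and its initial condition", {
  Gh <- deposition_stretch_fiber(1.1, c(0, 1, 0))
  # at t0: F = I, F_g = I, F_r = G_h^-1  =>  F_el = G_h
  expect_equal(elastic_deformation(diag(3), diag(3), solve(Gh)), Gh)
  F <- diag(c(0.95, 1.2, 1.05))
  expect_equal(elastic_deformation(F), F)
  expect_error(elastic_deformation(F, matrix(0, 3, 3)), "singular")
})

test_that("the fourth invariant equals the squared elastic fiber stretch", {
  a0 <- c(0, cos(pi / 4), sin(pi / 4))
  Fg <- diag(c(1.2, 1, 1))
  Fr <- deposition_stretch_fiber(0.95, a0)
  # pure inelastic motion: F = F_r F_g gives zero elastic fiber strain
  expect_equal(fiber_fourth_invariant(Fr %*% Fg, a0, Fg, Fr), 1,
               tolerance = 1e-12)
  # uniaxial elastic stretch along the fiber
  lam <- 1.17
  P <- outer(a0, a0)
  F <- lam * P + (diag(3) - P)
  expect_equal(fiber_fourth_invariant(F, a0), lam^2, tolerance = 1e-12)
  # generic case against the brute-force |F_el a|^2 oracle
  set.seed(42)
  for (i in 1:20) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.08), 3, 3)
    if (det(F) <= 0.2) next
    Fgr <- Fr %*% Fg
    a <- drop(Fgr %*% a0); a <- a / sqrt(sum(a^2))
    oracle <- sum((F %*% solve(Fgr) %*% a)^2)
    expect_equal(fiber_fourth_invariant(F, a0, Fg, Fr), oracle,
                 tolerance = 1e-12)
  }
})

test_that("elastin stress vanishes for rigid rotations and at identity", {
  p <- elastin_params()
  expect_equal(elastin_cauchy_stress(diag(3), 250, 1, p), matrix(0, 3, 3))
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  expect_equal(elastin_cauchy_stress(Q, 250, 1, p), matrix(0, 3, 3),
               tolerance = 1e-9)
})

test_that("fiber passive stress is rank-one, zero at I4 = 1, increasing in I4", {
  p <- fiber_params(k1_t = 105, k2_t = 0.13)
  a0 <- c(0, 1, 0)
  expect_equal(fiber_passive_cauchy_stress(diag(3), a0, 100, p),
               matrix(0, 3, 3))
  F <- diag(c(0.95, 1.15, 1.02))
  s <- fiber_passive_cauchy_stress(F, a0, 120, p)
  ev <- eigen(s, symmetric = TRUE)$values
  expect_equal(sum(abs(ev) > 1e-9 * max(abs(ev))), 1)  # rank one
  # scalar factor example: I4 = 1.21 at spatial density 100 kg/m^3
  Fs <- diag(c(1, 1.1, 1))
  sig <- fiber_passive_cauchy_stress(Fs, a0, 100 * det(Fs), p)
  expect_equal(sig[2, 2], 2 * 100 * 105 * 0.21 * exp(0.13 * 0.21^2) * 1.21,
               tolerance = 1e-12)
  # strictly increasing fiber stress for I4 > 1
  lams <- seq(1.01, 1.4, by = 0.01)
  fib <- vapply(lams, function(l) {
    fiber_passive_cauchy_stress(diag(c(1, l, 1)), a0, 100, p)[2, 2]
  }, numeric(1))
  expect_true(all(diff(fib) > 0))
})

test_that("the active length-tension parabola has the printed geometry", {
  p <- active_params(lambda_max = 1.4, lambda_zero = 0.8)
  expect_identical(active_stress_factor(1.4, p), 1)
  expect_identical(active_stress_factor(0.8, p), 0)
  expect_equal(active_stress_factor(1 / 1.1, p), 0.330578512396694,
               tolerance = 1e-12)
  # symmetric about lambda_max, never above 1
  d <- runif(20, 0, 0.55)
  expect_equal(active_stress_factor(1.4 + d, p),
               active_stress_factor(1.4 - d, p))
  expect_true(all(active_stress_factor(seq(0.2, 2.5, by = 0.01), p) <= 1))
  # clamping: zero beyond both parabola roots
  expect_identical(active_stress_factor(2.1, p), 0)
  p_noclamp <- active_params(lambda_max = 1.4, clamp_negative = FALSE)
  expect_lt(active_stress_factor(2.1, p_noclamp), 0)
  expect_error(active_params(lambda_max = 0.8, lambda_zero = 0.8),
               "strictly greater")
})

test_that("SMC active stress magnitude matches direct evaluation", {
  p <- active_params()
  a0 <- c(0, 1, 0)
  sig <- smc_active_cauchy_stress(diag(3), a0, 280, 990, p, lambda0_m = 1.1)
  f <- 1 - (1.4 - 1 / 1.1)^2 / 0.36
  expect_equal(sig[2, 2], 280 / 990 * 54000 * f, tolerance = 1e-12)
  expect_equal(sig[2, 2], 5048.83546, tolerance = 1e-6)
  # clamped regime gives a zero tensor
  F <- diag(c(1, 2.5, 1))
  expect_equal(smc_active_cauchy_stress(F, a0, 280, 990, p),
               matrix(0, 3, 3))
})

test_that("mixture stress is the density-linear sum of constituent stresses", {
  params <- mixture_params()
  pt <- material_point(params, "media")
  F <- diag(c(0.97, 1.08, 1.03))
  s1 <- mixture_cauchy_stress(pt, F, params)
  # zero densities -> zero stress
  pt0 <- pt
  pt0$rho_e <- 0; pt0$rho_c <- rep(0, 4); pt0$rho_m <- 0
  expect_equal(mixture_cauchy_stress(pt0, F, params), matrix(0, 3, 3))
  # doubling every density doubles the stress
  pt2 <- pt
  pt2$rho_e <- 2 * pt$rho_e; pt2$rho_c <- 2 * pt$rho_c
  pt2$rho_m <- 2 * pt$rho_m
  expect_equal(mixture_cauchy_stress(pt2, F, params), 2 * s1,
               tolerance = 1e-12)
  # scaling only elastin changes only the elastin share
  pt_e <- pt
  pt_e$rho_e <- 2 * pt$rho_e
  st <- constituent_stresses(pt, F, params)
  st_e <- constituent_stresses(pt_e, F, params)
  expect_equal(st_e$elastin, 2 * st$elastin, tolerance = 1e-12)
  expect_equal(st_e$smc_passive, st$smc_passive)
})

test_that("each constituent stress is the derivative of its strain energy", {
  params <- mixture_params()
  set.seed(7)
  for (i in 1:10) {
    pt <- random_point(params)
    F <- random_deformation()
    st <- constituent_stresses(pt, F, params)
    Fg <- diag(c(pt$g_rr, 1, 1))
    # elastin
    W_e <- function(Fx) {
      pt$rho_e * elastin_energy(
        elastic_deformation(Fx, Fg, diag(1 / pt$gh_e)), params$elastin)
    }
    expect_lt(rel_err(fd_cauchy(W_e, F), st$elastin), 1e-5)
    # one collagen family (diagonal, j = 3)
    a0 <- c(0, cos(pi / 4), sin(pi / 4))
    Fr <- remodeling_tensor(pt$lam_r_c[3], a0)
    W_c <- function(Fx) {
      pt$rho_c[3] * fiber_energy(fiber_fourth_invariant(Fx, a0, Fg, Fr),
                                 params$collagen)
    }
    expect_lt(rel_err(fd_cauchy(W_c, F), st$collagen[[3]]), 1e-5)
    # total mixture energy against the summed stress
    W_tot <- function(Fx) point_strain_energy(pt, Fx, params)
    expect_lt(rel_err(fd_cauchy(W_tot, F), st$total), 1e-5)
  }
})
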