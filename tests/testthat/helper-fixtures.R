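# shared fixtures: cached expensive objects (homeostatic initializations,
# reference runs) live for the whole test session
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# initialized two-layer vessel at a given maximal active stretch
init_vessel <- function(lambda_max = 1.4) {
  cached(paste0("vessel_", lambda_max), {
    p <- mixture_params(active = active_params(lambda_max = lambda_max))
    init_homeostatic(build_two_layer_cylinder(vessel_config(), p))
  })
}

# worst-case damaged run (full horizon, no early stop)
worst_case_run <- function() {
  cached("worst_case_traj", {
    run_simulation(init_vessel(1.0), damage_params(D_max = 0.5, t_dam = 40),
                   horizon_months = 180, stop_on_convergence = FALSE)
  })
}

# a random admissible material point state (fiber constituents perturbed
# around their deposition configuration, mild growth, positive densities)
random_point <- function(params) {
  pt <- material_point(params, layer = "media")
  pt$rho_e <- runif(1, 100, 300)
  pt$rho_c <- runif(4, 50, 200)
  pt$rho_m <- runif(1, 100, 300)
  pt$lam_r_c <- (1 / params$collagen$lambda0) * exp(runif(4, -0.05, 0.05))
  pt$lam_r_m <- (1 / params$smc$lambda0) * exp(runif(1, -0.05, 0.05))
  pt$g_rr <- exp(runif(1, -0.05, 0.05))
  pt$rho_tot_init <- pt$rho_e + sum(pt$rho_c) + pt$rho_m
  set_homeostatic_targets(pt, params)
}

# a random total deformation gradient close to a physiological state; kept
# away from the I4 = 1 tension/compression kink and the active-stress clamp
random_deformation <- function() {
  F <- diag(c(exp(runif(1, -0.08, 0.02)), exp(runif(1, 0.02, 0.12)),
              exp(runif(1, 0.01, 0.08))))
  F[2, 3] <- runif(1, 0, 0.05)
  F
}

# finite-difference first Piola-Kirchhoff stress of an energy W(F),
# pushed forward to a Cauchy stress
fd_cauchy <- function(W_fun, F, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (W_fun(Fp) - W_fun(Fm)) / (2 * h)
    }
  }
  P %*% t(F) / det(F)
}

rel_err <- function(a, b) {
  d <- max(abs(a - b))
  d / max(max(abs(b)), 1e-8)
}
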