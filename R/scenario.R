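#' Active stress ratios along a trajectory
#'
#' The contribution of SMC active tone to the stress field, reported as two
#' ratios on circumferential Cauchy components: `R_m = sigma_act / sigma_m`
#' (active over total SMC stress, averaged over the SMC-bearing media) and
#' `R_t = sigma_act / sigma_t` (active over total mixture stress, averaged
#' over the whole wall). Ratios are flagged `NA` where the denominator is
#' non-positive while the numerator is not.
#'
#' @param traj A `gr_trajectory` from [run_simulation()].
#' @return A tibble with columns `month`, `R_m`, `R_t` (wall-averaged,
#'   dimensionless) and `shells`, a list-column of element-wise ratios.
#' @export
stress_ratios <- function(traj) {
  per_shell <- purrr::map(traj$shells, function(sh) {
    ratio <- function(num, den) {
      dplyr::if_else(den > 0, num / den,
                     dplyr::if_else(num == 0, 0, NA_real_))
    }
    tibble::tibble(shell = sh$shell, layer = sh$layer,
                   R_m = ratio(sh$stt_active, sh$stt_smc),
                   R_t = ratio(sh$stt_active, sh$stt))
  })
  tibble::tibble(month = traj$month, R_m = traj$R_m, R_t = traj$R_t,
                 shells = per_shell)
}

#' Diameter and thickness evolution
#'
#' @param traj A `gr_trajectory`.
#' @return A tibble with `month`, inner `diameter` (m) and wall
#'   `thickness` (m).
#' @export
geometry_series <- function(traj) {
  tibble::tibble(month = traj$month, diameter = 2 * traj$r_inner,
                 thickness = traj$thickness)
}

#' SMC active stress-stretch curve
#'
#' Pairs the SMC stretch with the circumferential active Cauchy stress at
#' the probe shell (mid-media of the damage-center ring) over the run; the
#' first point sits at the homeostatic reference `lambda_m = 1`.
#'
#' @param traj A `gr_trajectory`.
#' @return A tibble with `month`, `lambda_m`, `sigma_active` (Pa) and the
#'   length-tension factor `f_act`.
#' @export
stress_stretch_curve <- function(traj) {
  tibble::tibble(month = traj$month, lambda_m = traj$lambda_m_probe,
                 sigma_active = traj$stress_active_probe,
                 f_act = traj$f_act_probe)
}

#' Sensitivity sweep over damage time, collagen gain and contractility
#'
#' Runs one simulation per grid cell of (`t_dam`, `k_sigma`, `lambda_max`),
#' re-initializing homeostasis for every `lambda_max` (the active tone
#' enters the homeostatic state). Cell failures are recorded and the sweep
#' continues.
#'
#' @param grid A [sweep_grid()] object.
#' @param cfg A [vessel_config()] object.
#' @param params A [mixture_params()] base parameter set.
#' @param damage A [damage_params()] base damage description (its `t_dam`
#'   is overridden cell-wise).
#' @param settings A [solve_settings()] object.
#' @param horizon_months Months per run.
#' @param stop_on_convergence Passed to [run_simulation()].
#' @return A tibble with class `"gr_sweep"`: one row per grid cell with
#'   final geometry, stress-ratio summaries and convergence information.
#' @export
sensitivity_sweep <- function(grid = sweep_grid(), cfg = vessel_config(),
                              params = mixture_params(),
                              damage = damage_params(),
                              settings = solve_settings(),
                              horizon_months = 180,
                              stop_on_convergence = TRUE) {
  cells <- tidyr::expand_grid(lambda_max = grid$lambda_max_values,
                              t_dam = grid$t_dam_values,
                              k_sigma = grid$k_sigma_values)
  res <- vector("list", nrow(cells))
  vessel <- NULL
  lam_cached <- NA_real_
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    out <- tryCatch({
      if (!identical(cell$lambda_max, lam_cached)) {
        p <- params
        p$active <- active_params(
          sigma_act_max = params$active$sigma_act_max,
          lambda_max = cell$lambda_max,
          lambda_zero = params$active$lambda_zero,
          clamp_negative = params$active$clamp_negative)
        vessel <- init_homeostatic(build_two_layer_cylinder(cfg, p),
                                   settings)
        lam_cached <- cell$lambda_max
      }
      p_run <- vessel$params
      p_run$collagen$k_sigma <- cell$k_sigma
      v_run <- vessel
      v_run$params <- p_run
      d <- damage
      d$t_dam <- cell$t_dam
      traj <- run_simulation(v_run, d, horizon_months, settings,
                             stop_on_convergence)
      g <- glance(traj)
      dplyr::bind_cols(cell, g,
                       tibble::tibble(ok = !attr(traj, "failed"),
                                      message = attr(traj,
                                                     "failure_message")))
    }, error = function(e) {
      dplyr::bind_cols(cell,
                       tibble::tibble(ok = FALSE,
                                      message = conditionMessage(e)))
    })
    res[[i]] <- out
  }
  out <- dplyr::bind_rows(res)
  tibble::new_tibble(out, class = "gr_sweep", nrow = nrow(out))
}
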