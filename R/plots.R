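#' Plot a growth-and-remodeling trajectory
#'
#' Faceted evolution of diameter, thickness, stress ratios and active SMC
#' stress over the run.
#'
#' @param object A `gr_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gr_trajectory <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::transmute(
      month = .data$month,
      `diameter [mm]` = 2e3 * .data$r_inner,
      `thickness [mm]` = 1e3 * .data$thickness,
      `active stress [kPa]` = .data$mean_stress_active / 1e3,
      `R_m [-]` = .data$R_m,
      `R_t [-]` = .data$R_t) |>
    tidyr::pivot_longer(-"month")
  ggplot2::ggplot(dat, ggplot2::aes(.data$month, .data$value)) +
    ggplot2::geom_line(color = "#2c5f8a") +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "time [months]", y = NULL,
                  title = "Growth and remodeling evolution") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' Final diameter against the collagen gain, faceted by damage time, one
#' line per maximal contractility.
#'
#' @param object A `gr_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gr_sweep <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$ok)
  ggplot2::ggplot(dat,
                  ggplot2::aes(.data$k_sigma, 1e3 * .data$final_diameter,
                               color = factor(.data$lambda_max))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~t_dam, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "collagen gain k_sigma [-]",
                  y = "final inner diameter [mm]",
                  color = "lambda_max") +
    ggplot2::theme_minimal()
}

#' Plot the SMC stress-stretch curve
#'
#' @param traj A `gr_trajectory`.
#' @return A ggplot object.
#' @export
plot_stress_stretch <- function(traj) {
  dat <- stress_stretch_curve(traj)
  ggplot2::ggplot(dat, ggplot2::aes(.data$lambda_m,
                                    .data$sigma_active / 1e3)) +
    ggplot2::geom_path(color = "#a03030") +
    ggplot2::labs(x = "SMC stretch lambda_m [-]",
                  y = "active circumferential stress [kPa]") +
    ggplot2::theme_minimal()
}
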