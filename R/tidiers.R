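#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a growth-and-remodeling trajectory
#'
#' Long format: one row per month and recorded quantity.
#'
#' @param x A `gr_trajectory`.
#' @param ... Unused.
#' @return A tibble with `month`, `name`, `value`.
#' @export
tidy.gr_trajectory <- function(x, ...) {
  x |>
    dplyr::select(-dplyr::any_of("shells")) |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(-"month")
}

#' One-row summary of a trajectory
#'
#' @param x A `gr_trajectory`.
#' @param ... Unused.
#' @return A tibble with final geometry, stress-ratio summaries, the active
#'   stress extrema and convergence information.
#' @export
glance.gr_trajectory <- function(x, ...) {
  last <- x[nrow(x), ]
  tibble::tibble(
    months_run = attr(x, "months_run"),
    final_diameter = 2 * last$r_inner,
    final_thickness = last$thickness,
    final_R_m = last$R_m, final_R_t = last$R_t,
    mean_R_m = mean(x$R_m), mean_R_t = mean(x$R_t),
    min_R_t = min(x$R_t), min_active = min(x$mean_stress_active),
    max_active = max(x$mean_stress_active),
    max_lambda_m = max(x$lambda_m_probe),
    stopped_early = isTRUE(attr(x, "stopped_early")),
    failed = isTRUE(attr(x, "failed")))
}

#' @rdname tidy.gr_trajectory
#' @export
tidy.gr_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a sensitivity sweep
#'
#' @param x A `gr_sweep`.
#' @param ... Unused.
#' @return A tibble with grid size, failures, and the range of final
#'   diameters.
#' @export
glance.gr_sweep <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x), n_failed = sum(!x$ok),
                 min_final_diameter = suppressWarnings(
                   min(x$final_diameter, na.rm = TRUE)),
                 max_final_diameter = suppressWarnings(
                   max(x$final_diameter, na.rm = TRUE)))
}
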