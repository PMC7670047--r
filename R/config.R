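# quantity strings: "80 mmHg", "2.38 mm", "101 years" -> SI value
parse_quantity <- function(x, target = c("Pa", "m", "days", "1")) {
  target <- match.arg(target)
  if (is.numeric(x)) {
    return(x)
  }
  m <- regmatches(x, regexec(
    "^\\s*(-?[0-9.eE+-]+)\\s*([A-Za-z]*)\\s*$", x))[[1]]
  if (length(m) != 3) {
    stop("Cannot parse quantity: '", x, "'.", call. = FALSE)
  }
  val <- as.numeric(m[2])
  unit <- m[3]
  conv <- switch(target,
    Pa = c(Pa = 1, kPa = 1e3, MPa = 1e6, mmHg = 133.322),
    m = c(m = 1, mm = 1e-3, cm = 1e-2, um = 1e-6),
    days = c(days = 1, day = 1, d = 1, months = 30, month = 30,
             years = 365, year = 365, y = 365),
    "1" = c(`1` = 1))
  if (unit == "") {
    return(val)
  }
  if (!unit %in% names(conv)) {
    stop("Unknown unit '", unit, "' for a ", target, " quantity.",
         call. = FALSE)
  }
  val * conv[[unit]]
}

#' Named presets of complete run configurations
#'
#' * `table1_best_case`: full two-layer model, maximal contractility
#'   `lambda_max = 1.4`.
#' * `table1_worst_case`: `lambda_max = 1.0` (the critical condition in
#'   which the active stress can collapse to zero).
#' * `homeostatic_control`: damage disabled and elastin background turnover
#'   off; the homeostatic fixed point.
#' * `thinwall_verification`: single-constituent (elastin) thin-walled tube
#'   with `h/r = 0.01` for the Laplace-law check.
#'
#' @param name Preset name.
#' @return A list with class `"run_config"` holding `vessel`, `materials`,
#'   `damage`, `solver`, `sweep` and `horizon_months`.
#' @export
make_preset <- function(name = c("table1_best_case", "table1_worst_case",
                                 "homeostatic_control",
                                 "thinwall_verification")) {
  known <- eval(formals(make_preset)$name)
  if (!is.character(name) || !name[1] %in% known) {
    stop("Unknown preset '", name[1], "'. Available presets: ",
         paste(known, collapse = ", "), ".", call. = FALSE)
  }
  name <- match.arg(name)
  cfg <- list(vessel = vessel_config(), materials = mixture_params(),
              damage = damage_params(), solver = solve_settings(),
              sweep = sweep_grid(), horizon_months = 180)
  if (name == "table1_worst_case") {
    cfg$materials$active <- active_params(lambda_max = 1.0)
  }
  if (name == "homeostatic_control") {
    cfg$damage <- damage_params(D_max = 0, enabled = FALSE)
    cfg$materials$elastin <- elastin_params(T_e_days = Inf)
    cfg$horizon_months <- 24
  }
  if (name == "thinwall_verification") {
    r <- 12.5e-3
    # moderate pressure keeps the pure-elastin membrane at a physiological
    # stretch while h/r = 0.01 realizes the Laplace limit
    cfg$vessel <- vessel_config(inner_radius = r, wall_thickness = 0.01 * r,
                                media_fraction = 1,
                                n_shells_media = 10,
                                n_shells_adventitia = 0, lambda0_ez = 1,
                                pressure = 50)
    cfg$materials <- mixture_params(
      elastin = elastin_params(lambda0_z = 1, T_e_days = Inf),
      rho0_collagen = 0, rho0_smc = 0,
      active = active_params(sigma_act_max = 0))
    cfg$damage <- damage_params(D_max = 0, enabled = FALSE)
    # the near-incompressible membrane limit is stiff radially; certify
    # the prestress fixed point at the attainable displacement level
    cfg$solver <- solve_settings(init_tol = 1e-7)
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Any omitted field falls back to the package defaults (an empty file gives
#' the full default configuration). Physical quantities may carry unit
#' strings (`pressure: 80 mmHg`, `wall_thickness: 2.38 mm`,
#' `t_dam: 40 days`); they are converted to SI on load. Invariants (for
#' instance `lambda_max > lambda_zero`) are enforced by the constructors.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  pick <- function(section, field, target = NULL, default) {
    v <- y[[section]][[field]]
    if (is.null(v)) {
      return(default)
    }
    if (!is.null(target)) parse_quantity(v, target) else v
  }
  materials <- mixture_params(
    elastin = elastin_params(
      mu_e = pick("materials", "mu_e", default = 82),
      kappa = pick("materials", "kappa",
                   default = 100 * pick("materials", "mu_e", default = 82)),
      lambda0_z = pick("materials", "lambda0_ez", default = 1.3),
      T_e_days = pick("materials", "T_e", "days", 101 * 365)),
    collagen = fiber_params(
      k1_t = pick("materials", "k1_c_t", default = 105),
      k2_t = pick("materials", "k2_c_t", default = 0.13),
      k1_c = pick("materials", "k1_comp", default = 15),
      k2_c = pick("materials", "k2_comp", default = 1),
      lambda0 = pick("materials", "lambda0_c", default = 1.1),
      T_days = pick("materials", "T_c", "days", 101),
      k_sigma = pick("materials", "k_sigma", default = 0.05)),
    smc = fiber_params(
      k1_t = pick("materials", "k1_m_t", default = 10),
      k2_t = pick("materials", "k2_m_t", default = 0.1),
      k1_c = pick("materials", "k1_comp", default = 15),
      k2_c = pick("materials", "k2_comp", default = 1),
      lambda0 = pick("materials", "lambda0_m", default = 1.1),
      T_days = pick("materials", "T_m", "days", 101)),
    active = active_params(
      sigma_act_max = pick("materials", "sigma_act_max", "Pa", 54e3),
      lambda_max = pick("materials", "lambda_max", default = 1.4),
      lambda_zero = pick("materials", "lambda_zero", default = 0.8)),
    rho0_elastin = pick("materials", "rho0_elastin", default = 250),
    rho0_collagen = pick("materials", "rho0_collagen", default = 460),
    rho0_smc = pick("materials", "rho0_smc", default = 280))
  vessel <- vessel_config(
    inner_radius = pick("vessel", "inner_radius", "m", 12.5e-3),
    wall_thickness = pick("vessel", "wall_thickness", "m", 2.38e-3),
    media_fraction = pick("vessel", "media_fraction", default = 2 / 3),
    n_shells_media = pick("vessel", "n_shells_media", default = 6),
    n_shells_adventitia = pick("vessel", "n_shells_adventitia",
                               default = 4),
    n_rings_axial = pick("vessel", "n_rings_axial", default = 1),
    length = pick("vessel", "length", "m", 0.04),
    pressure = pick("vessel", "pressure", "Pa", 80 * 133.322),
    lambda0_ez = pick("materials", "lambda0_ez", default = 1.3))
  damage <- damage_params(
    D_max = pick("damage", "D_max", default = 0.5),
    t_dam = pick("damage", "t_dam", "days", 40),
    L_dam = pick("damage", "L_dam", "m", 0.01),
    center = pick("damage", "center", "m", 0),
    enabled = pick("damage", "enabled", default = TRUE))
  solver <- solve_settings(
    newton_tol = pick("solver", "newton_tol", "Pa", 1e-4),
    max_newton_iter = pick("solver", "max_newton_iter", default = 60),
    init_tol = pick("solver", "init_tol", "m", 1e-9),
    conv_threshold = pick("solver", "conv_threshold", default = 0.01),
    thickness_norm_T = pick("solver", "thickness_norm_T", "m", 2.5e-3),
    dt_days = pick("solver", "dt", "days", 30))
  swp <- sweep_grid(
    t_dam_values = vapply(
      pick("sweep", "t_dam_values", default = list(20, 40, 80)),
      parse_quantity, numeric(1), target = "days"),
    k_sigma_values = unlist(pick("sweep", "k_sigma_values",
                                 default = list(0.05, 0.15, 0.30))),
    lambda_max_values = unlist(pick("sweep", "lambda_max_values",
                                    default = list(1, 1.1, 1.4))))
  structure(list(vessel = vessel, materials = materials, damage = damage,
                 solver = solver, sweep = swp,
                 horizon_months = pick("run", "horizon_months",
                                       default = 180)),
            class = "run_config")
}

#' Write outputs of a run to disk
#'
#' Writes `summary.csv` (one row per month, headers carry units),
#' `shells_final.csv` (per-shell state at the final step) and
#' `manifest.json` (the fully resolved configuration, for bit-identical
#' re-runs) for a trajectory; for a sweep, `sweep.csv` and the manifest.
#'
#' @param x A `gr_trajectory` or `gr_sweep`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "vesselgr",
    version = as.character(utils::packageVersion("vesselgr")),
    months_per_step = 1, days_per_month = 30,
    cfg = attr(x, "cfg"), damage = attr(x, "damage"),
    settings = attr(x, "settings"))
  paths <- character(0)
  if (inherits(x, "gr_trajectory")) {
    p1 <- file.path(dir, "summary.csv")
    flat <- dplyr::select(tibble::as_tibble(x), -dplyr::any_of("shells"))
    utils::write.csv(flat, p1, row.names = FALSE)
    p2 <- file.path(dir, "shells_final.csv")
    utils::write.csv(x$shells[[nrow(x)]], p2, row.names = FALSE)
    paths <- c(p1, p2)
  } else if (inherits(x, "gr_sweep")) {
    p1 <- file.path(dir, "sweep.csv")
    utils::write.csv(tibble::as_tibble(x), p1, row.names = FALSE)
    paths <- p1
  } else {
    stop("`x` must be a gr_trajectory or gr_sweep.", call. = FALSE)
  }
  pm <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(paths, pm))
}
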