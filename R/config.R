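# Plain-text (YAML) run configuration. All physical quantities carry their
# units in the key name; unknown keys are rejected for typo safety.

.config_schema <- list(
  scenario = c("type", "h_um", "domain_width_um", "domain_height_um",
               "disc_radius_um", "bm_radius_um", "tumor_cell_radius_um",
               "n_tumor_cells", "stromal_cell_radius_um",
               "stromal_angles_deg", "stromal_offset_um", "length_um",
               "freeze_E"),
  params = c("D0", "D0_units", "rM_per_s", "rE_per_s", "dM_per_s",
             "E_init", "M_boundary", "source_per_s"),
  solver = c("dt_safety", "theta_min", "snapshot_interval_s", "t_end_s",
             "engine"),
  metrics = c("threshold_fraction", "fit_start_min", "fit_end_min"),
  output = c("dir", "format")
)

.default_config_values <- function() {
  list(
    scenario = list(type = "single_source", h_um = 1,
                    domain_width_um = 200, domain_height_um = 200,
                    disc_radius_um = 5, bm_radius_um = 40,
                    tumor_cell_radius_um = 5, n_tumor_cells = NULL,
                    stromal_cell_radius_um = 5,
                    stromal_angles_deg = c(70, 90, 110),
                    stromal_offset_um = 10, length_um = 100,
                    freeze_E = FALSE),
    params = list(D0 = 8e-9, D0_units = "cm2_per_s", rM_per_s = 1 / 200,
                  rE_per_s = 1 / 200, dM_per_s = 5e-5, E_init = 0.85,
                  M_boundary = 1, source_per_s = 0),
    solver = list(dt_safety = 0.8, theta_min = 0.3,
                  snapshot_interval_s = 60, t_end_s = 2400,
                  engine = "cpp"),
    metrics = list(threshold_fraction = 0.5, fit_start_min = 15,
                   fit_end_min = 40),
    output = list(dir = "mmpdeg_output", format = "text")
  )
}

#' Load and validate a run configuration
#'
#' Reads the package's YAML configuration dialect, rejects unknown sections
#' or keys by name, fills missing values with the standard defaults
#' (D0 = 8e-9 cm^2/s, rM = rE = 1/200 /s, dM = 5e-5 /s, E_init = 0.85,
#' M = 1 on secreting cells), and validates physical invariants. An empty
#' file yields the full default configuration.
#'
#' @param path path to a YAML config file, or `NULL` for pure defaults.
#' @return a `run_config` list with sections `scenario`, `params`, `solver`,
#'   `metrics`, `output`, and the constructed `kinetic_params` object in
#'   `$kp`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config file does not parse to a mapping: ",
                             path)
  }
  cfg <- .default_config_values()
  for (section in names(user)) {
    if (!section %in% names(.config_schema))
      stop("unknown config section: ", section)
    keys <- names(user[[section]])
    bad <- setdiff(keys, .config_schema[[section]])
    if (length(bad))
      stop("unknown config key: ", section, ".", bad[1])
    cfg[[section]] <- modifyList(cfg[[section]], user[[section]],
                                 keep.null = TRUE)
  }
  p <- cfg$params
  cfg$kp <- kinetic_params(D0 = p$D0, D0_units = p$D0_units,
                           rM = p$rM_per_s, rE = p$rE_per_s, dM = p$dM_per_s,
                           E_init = p$E_init, M_boundary = p$M_boundary,
                           source_s = p$source_per_s)
  if (!cfg$scenario$type %in% c("single_source", "duct", "column_1d"))
    stop("scenario.type must be one of single_source, duct, column_1d")
  f <- cfg$metrics$threshold_fraction
  if (!(f > 0 && f < 1)) stop("metrics.threshold_fraction must be in (0, 1)")
  structure(cfg, class = "run_config")
}

#' Build the scenario described by a run configuration
#' @param cfg a `run_config` from [load_config()].
#' @return a `scenario`.
#' @export
scenario_from_config <- function(cfg) {
  s <- cfg$scenario
  switch(s$type,
    single_source = build_single_source_scenario(
      h = s$h_um, domain_um = c(s$domain_width_um, s$domain_height_um),
      disc_radius_um = s$disc_radius_um, params = cfg$kp),
    duct = build_duct_scenario(
      h = s$h_um, domain_um = c(s$domain_width_um, s$domain_height_um),
      bm_radius_um = s$bm_radius_um,
      tumor_cell_radius_um = s$tumor_cell_radius_um,
      n_tumor_cells = s$n_tumor_cells,
      stromal_cell_radius_um = s$stromal_cell_radius_um,
      stromal_angles_deg = s$stromal_angles_deg,
      stromal_offset_um = s$stromal_offset_um, params = cfg$kp),
    column_1d = build_1d_column_scenario(
      length_um = s$length_um, h = s$h_um, freeze_E = s$freeze_E,
      params = cfg$kp)
  )
}

#' Solver configuration described by a run configuration
#' @param cfg a `run_config`.
#' @return a [solver_config()].
#' @export
solver_config_from_config <- function(cfg) {
  s <- cfg$solver
  solver_config(dt_safety = s$dt_safety, theta_min = s$theta_min,
                snapshot_interval_s = s$snapshot_interval_s,
                t_end_s = s$t_end_s, engine = s$engine)
}
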