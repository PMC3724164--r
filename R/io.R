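# Text output of runs: summary CSV, field snapshots, provenance record.

.write_field <- function(m, path, t_s, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# field = %s, t_s = %g, nx = %d, ny = %d", what, t_s,
                     nrow(m), ncol(m)), con)
  utils::write.table(t(m), con, row.names = FALSE, col.names = FALSE,
                     sep = ",")
}

#' Write the outputs of a run to a directory
#'
#' Writes `summary.csv` (one row per snapshot), per-snapshot field matrices
#' as header-commented delimited text (`M_t<min>min.csv`, `E_t<min>min.csv`;
#' rows are y, columns are x), and a `provenance.yaml` record (package
#' version, derived time step, configuration echo) sufficient to reproduce
#' the run.
#'
#' @param run an `mmp_run`.
#' @param dir output directory (created if missing).
#' @param fields also write the field snapshots (requires kept fields).
#' @param config optional `run_config` to echo into the provenance record.
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir, fields = TRUE, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  utils::write.csv(run$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (fields && !is.null(run$snapshots)) {
    for (s in run$snapshots) {
      tag <- sprintf("t%04gmin", s$t / 60)
      .write_field(s$M, file.path(dir, paste0("M_", tag, ".csv")), s$t, "M")
      .write_field(s$E, file.path(dir, paste0("E_", tag, ".csv")), s$t, "E")
    }
  }
  prov <- list(package = "mmpdeg",
               version = as.character(utils::packageVersion("mmpdeg")),
               scenario_id = run$scenario$id,
               dt_s = run$dt_s,
               threshold_fraction = run$threshold_fraction)
  if (!is.null(config))
    prov$config <- config[setdiff(names(config), "kp")]
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Heat-map plot of a field snapshot
#'
#' Minimal visualization helper: `graphics::image()` of M or E with correct
#' physical axes (um).
#'
#' @param state a `field_state`.
#' @param scenario the `scenario` the state lives on.
#' @param what `"E"` or `"M"`.
#' @param ... passed to [graphics::image()].
#' @export
plot_field <- function(state, scenario, what = c("E", "M"), ...) {
  what <- match.arg(what)
  g <- scenario$grid
  graphics::image(g$x, g$y, state[[what]], xlab = "x (um)", ylab = "y (um)",
                  main = sprintf("%s at t = %g min", what, state$t / 60),
                  useRaster = TRUE, asp = 1, ...)
  invisible(state)
}
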