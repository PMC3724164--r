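# Ghost-fluid finite-difference integration of the MMP-ECM system.

#' Solver configuration
#'
#' @param dt_safety fraction of the explicit diffusive stability limit used
#'   for the time step (0 < dt_safety <= 1, default 0.8).
#' @param theta_min lower clamp on the sub-cell interface fraction theta used
#'   in the Dirichlet ghost extrapolation (0 < theta_min < 0.5, default 0.3).
#'   The clamp keeps the ghost term inside the explicit stability region:
#'   the face coefficient scales as dt * D0 / (theta * h^2), so theta below
#'   roughly 4 * dt_safety * D0 * dt / h^2 would destabilize the scheme.
#' @param snapshot_interval_s seconds between recorded snapshots.
#' @param t_end_s total simulated time, s.
#' @param engine `"cpp"` (compiled stencil) or `"reference"` (pure-R stencil,
#'   for cross-checking on small grids).
#' @return a `solver_config` object.
#' @export
solver_config <- function(dt_safety = 0.8, theta_min = 0.3,
                          snapshot_interval_s = 60, t_end_s = 2400,
                          engine = c("cpp", "reference")) {
  engine <- match.arg(engine)
  if (!(dt_safety > 0 && dt_safety <= 1)) stop("dt_safety must be in (0, 1]")
  if (!(theta_min > 0 && theta_min < 0.5))
    stop("theta_min must be in (0, 0.5)")
  if (snapshot_interval_s <= 0) stop("snapshot_interval_s must be > 0")
  if (t_end_s < 0) stop("t_end_s must be >= 0")
  structure(list(dt_safety = dt_safety, theta_min = theta_min,
                 snapshot_interval_s = snapshot_interval_s,
                 t_end_s = t_end_s, engine = engine),
            class = "solver_config")
}

#' Stable explicit time step
#'
#' Diffusive stability limit of the explicit 5-point scheme, scaled by the
#' safety factor: `dt = dt_safety * h^2 / (4 * D0)` in 2-D (`2 * D0` for a
#' 1-D column). D0 bounds D(E) = D0(1 - E) from above, so the limit holds
#' for all ECM states reached during a run.
#'
#' @param params a [kinetic_params()].
#' @param grid a [grid_spec()].
#' @param config a [solver_config()] (only `dt_safety` and
#'   `snapshot_interval_s` are used).
#' @return time step in s.
#' @export
stable_dt <- function(params, grid, config = solver_config()) {
  if (params$D0 == 0) return(config$snapshot_interval_s)  # pure reaction
  denom <- if (grid$ny == 1) 2 * params$D0 else 4 * params$D0
  config$dt_safety * grid$h^2 / denom
}

# shift a matrix so out[i,j] = m[i+di, j+dj]; out-of-domain -> NA
.shift_mat <- function(m, di, dj) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(NA_real_, nx, ny)
  xi <- seq_len(nx) + di
  yj <- seq_len(ny) + dj
  okx <- xi >= 1 & xi <= nx
  oky <- yj >= 1 & yj <= ny
  out[okx, oky] <- m[xi[okx], yj[oky], drop = FALSE]
  out
}

#' Precompute the ghost-fluid stencil tables of a scenario
#'
#' Classifies each of the four stencil arms of every node against the
#' scenario's level sets: plain interior face, zero-flux mirror (arm crosses
#' the BM, an inert cell, or the domain boundary), or Dirichlet ghost (arm
#' enters a secreting cell), with the raw sub-cell fraction
#' theta = |phi_c| / (|phi_c| + |phi_n|) stored for ghost faces. Interfaces
#' are static, so this runs once per scenario.
#'
#' @param scenario a `scenario`.
#' @return a `stencil` list with per-direction integer code matrices and
#'   theta matrices.
#' @export
build_stencil <- function(scenario) {
  ps <- scenario$phi_secreting
  pin <- scenario$phi_inert
  pbm <- scenario$phi_bm
  dirs <- list(W = c(-1L, 0L), E = c(1L, 0L), S = c(0L, -1L), N = c(0L, 1L))
  codes <- list(); thetas <- list()
  for (d in names(dirs)) {
    di <- dirs[[d]][1]; dj <- dirs[[d]][2]
    ps_n <- .shift_mat(ps, di, dj)
    pin_n <- .shift_mat(pin, di, dj)
    pbm_n <- .shift_mat(pbm, di, dj)
    ood <- is.na(ps_n)
    side <- function(phi) phi > 0
    code <- matrix(0L, nrow(ps), ncol(ps))
    cr_inert <- !ood & (side(pin) != side(pin_n))
    cr_sec <- !ood & side(ps) & !side(ps_n)     # center outside, arm enters
    cr_bm <- !ood & (side(pbm) != side(pbm_n))
    code[cr_inert] <- 1L
    code[cr_sec] <- 2L
    code[cr_bm] <- 1L                            # BM takes precedence
    code[ood] <- 1L                              # domain boundary: zero flux
    den <- abs(ps) + abs(ps_n)
    th <- ifelse(is.finite(den) & den > 0, abs(ps) / den, 0.5)
    th[is.na(th) | code != 2L] <- 1
    codes[[d]] <- code
    thetas[[d]] <- th
  }
  structure(list(code = codes, theta = thetas, active = scenario$active),
            class = "stencil")
}

#' Dirichlet ghost value of the ghost-fluid method
#'
#' Linear extrapolation of the field through the interface point: with the
#' interface a fraction `theta` of the arm away from the center node,
#' `ghost = M_boundary / theta + (1 - 1/theta) * M_center`, so that the
#' value interpolated at the interface equals `M_boundary`.
#'
#' @param M_center field value at the center node.
#' @param M_boundary Dirichlet value on the interface.
#' @param theta sub-cell fraction in (0, 1].
#' @return the ghost value substituted for the neighbor.
#' @examples
#' gf_ghost_value(0, 1, 0.5)  # interface midway: ghost = 2
#' @export
gf_ghost_value <- function(M_center, M_boundary, theta) {
  if (any(theta <= 0) || any(theta > 1)) stop("theta must be in (0, 1]")
  M_boundary / theta + (1 - 1 / theta) * M_center
}

# pure-R reference stencil, identical semantics to the compiled kernel
.gf_diffusion_step_r <- function(M, D, st, dt, h, Mb, theta_min) {
  nx <- nrow(M); ny <- ncol(M)
  out <- M
  c0 <- dt / h^2
  nb <- list(W = c(-1L, 0L), E = c(1L, 0L), S = c(0L, -1L), N = c(0L, 1L))
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      if (!st$active[i, j]) next
      mc <- M[i, j]; dc <- D[i, j]
      flux <- 0
      for (d in names(nb)) {
        code <- st$code[[d]][i, j]
        if (code == 0L) {
          ii <- i + nb[[d]][1]; jj <- j + nb[[d]][2]
          flux <- flux + 0.5 * (dc + D[ii, jj]) * (M[ii, jj] - mc)
        } else if (code == 2L) {
          th <- max(st$theta[[d]][i, j], theta_min)
          flux <- flux + dc * (Mb - mc) / th
        }
      }
      v <- mc + c0 * flux
      if (v < 0 && v > -1e-12) v <- 0
      out[i, j] <- v
    }
  }
  out
}

#' One explicit ghost-fluid diffusion step of the MMP field
#'
#' Advances M by `dt` under the 5-point centered discretization of
#' \eqn{\nabla\cdot(D \nabla M)} with face diffusivity the arithmetic mean
#' of adjacent nodal D(E). Wherever a stencil arm crosses an interface, the
#' neighbor is replaced by a mirror value (zero-flux: BM, inert cells,
#' domain boundary) or a linearly extrapolated ghost value (Dirichlet:
#' secreting cells); see [gf_ghost_value()].
#'
#' @param M,E nx-by-ny field matrices.
#' @param scenario the `scenario` the fields live on.
#' @param stencil tables from [build_stencil()] (rebuilt if NULL).
#' @param dt time step, s; must not exceed [stable_dt()].
#' @param config a [solver_config()].
#' @return the updated M matrix.
#' @export
diffusion_step <- function(M, E, scenario, stencil = NULL, dt,
                           config = solver_config()) {
  if (is.null(stencil)) stencil <- build_stencil(scenario)
  dt_max <- stable_dt(scenario$params, scenario$grid, config)
  if (dt > dt_max * (1 + 1e-9))
    stop(sprintf("dt = %g s exceeds the stability limit %g s", dt, dt_max))
  D <- scenario$params$D0 * (1 - E)
  Mb <- scenario$params$M_boundary
  h <- scenario$grid$h
  M_new <- if (config$engine == "cpp") {
    gf_diffusion_step_cpp(M, D, stencil$active,
                          stencil$code$W, stencil$code$E,
                          stencil$code$S, stencil$code$N,
                          stencil$theta$W, stencil$theta$E,
                          stencil$theta$S, stencil$theta$N,
                          dt, h, Mb, config$theta_min)
  } else {
    .gf_diffusion_step_r(M, D, stencil, dt, h, Mb, config$theta_min)
  }
  bad <- which(!is.finite(M_new) | M_new < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(M_new))
    stop(sprintf(paste("diffusion step produced an invalid MMP value",
                       "(%g) at node (%d, %d)"),
                 M_new[bad[1]], ij[1] - 1L, ij[2] - 1L))
  }
  M_new
}

#' Exact-exponential reaction/decay update
#'
#' Local (per-node) update of the reaction and decay terms, integrated
#' exactly over `dt` with the partner field held at its step-start value:
#' `M <- M * exp(-(rM*E + dM) * dt)`, then `E <- E * exp(-rE*M * dt)`.
#' Unconditionally positivity-preserving; E is pointwise non-increasing.
#'
#' @param M,E field matrices.
#' @param params a [kinetic_params()].
#' @param dt time step, s.
#' @param freeze_E hold E fixed (validation runs).
#' @return list with updated `M` and `E`.
#' @export
reaction_decay_step <- function(M, E, params, dt, freeze_E = FALSE) {
  reaction_decay_step_cpp(M, E, params$rM, params$rE, params$dM, dt,
                          isTRUE(freeze_E))
}

#' One full solver step
#'
#' Applies [diffusion_step()] then [reaction_decay_step()], adds the
#' volumetric source term if nonzero, and re-imposes M = `M_boundary` on
#' nodes interior to secreting cells; advances t by `dt`.
#'
#' @param state a `field_state` list with `t`, `M`, `E`.
#' @param scenario a `scenario`.
#' @param stencil tables from [build_stencil()].
#' @param dt time step, s.
#' @param config a [solver_config()].
#' @return the updated `field_state`.
#' @export
solver_step <- function(state, scenario, stencil = NULL, dt,
                        config = solver_config()) {
  if (is.null(stencil)) stencil <- build_stencil(scenario)
  p <- scenario$params
  M <- diffusion_step(state$M, state$E, scenario, stencil, dt, config)
  if (any(p$source_s != 0))
    M[scenario$active] <- M[scenario$active] + dt * p$source_s
  M[scenario$inside_secreting] <- p$M_boundary
  upd <- reaction_decay_step(M, state$E, p, dt, scenario$freeze_E)
  M <- upd$M
  M[scenario$inside_secreting] <- p$M_boundary
  structure(list(t = state$t + dt, M = M, E = upd$E), class = "field_state")
}

#' Initial field state of a scenario
#' @param scenario a `scenario`.
#' @return a `field_state` with `t = 0` and the scenario's initial fields.
#' @export
initial_state <- function(scenario) {
  structure(list(t = 0, M = scenario$initial_M, E = scenario$initial_E),
            class = "field_state")
}

#' Run a simulation
#'
#' Integrates the scenario to `t_end_s`, emitting a snapshot every
#' `snapshot_interval_s`. The time step is the largest value not exceeding
#' [stable_dt()] that divides the snapshot interval exactly, so snapshot
#' times are hit without interpolation and runs are deterministic given
#' scenario + config.
#'
#' @param scenario a `scenario`.
#' @param config a [solver_config()].
#' @param keep_fields store the full M and E matrices of every snapshot
#'   (default TRUE); with FALSE only the summary table is kept.
#' @param threshold_fraction degraded-region threshold as a fraction of
#'   E_init, used for the per-snapshot summary (default 0.5).
#' @param progress print one line per simulated snapshot interval.
#' @return an `mmp_run` object: list with `summary` (data.frame: t_s, t_min,
#'   total_M, min_E, degraded_area_um2, equivalent_radius_um), `snapshots`
#'   (list of `field_state`, if kept), `dt_s`, `scenario`, `config`.
#' @export
run_simulation <- function(scenario, config = solver_config(),
                           keep_fields = TRUE, threshold_fraction = 0.5,
                           progress = FALSE) {
  stopifnot(inherits(scenario, "scenario"), inherits(config, "solver_config"))
  stencil <- build_stencil(scenario)
  dt_max <- stable_dt(scenario$params, scenario$grid, config)
  n_sub <- max(1L, ceiling(config$snapshot_interval_s / dt_max - 1e-12))
  dt <- config$snapshot_interval_s / n_sub
  n_snap <- ceiling(config$t_end_s / config$snapshot_interval_s - 1e-12)

  state <- initial_state(scenario)
  h <- scenario$grid$h
  summarize <- function(s) {
    mask <- degraded_mask(s$E, scenario, fraction = threshold_fraction)
    area <- sum(mask) * h^2
    data.frame(t_s = s$t, t_min = s$t / 60,
               total_M = sum(s$M) * h^2,
               min_E = if (any(scenario$stroma))
                 min(s$E[scenario$stroma]) else NA_real_,
               degraded_area_um2 = area,
               equivalent_radius_um = sqrt(area / pi))
  }
  rows <- vector("list", n_snap + 1)
  snaps <- if (keep_fields) vector("list", n_snap + 1) else NULL
  rows[[1]] <- summarize(state)
  if (keep_fields) snaps[[1]] <- state
  if (n_snap > 0) {
    for (k in seq_len(n_snap)) {
      for (s in seq_len(n_sub))
        state <- solver_step(state, scenario, stencil, dt, config)
      state$t <- k * config$snapshot_interval_s  # avoid drift accumulation
      rows[[k + 1]] <- summarize(state)
      if (keep_fields) snaps[[k + 1]] <- state
      if (progress)
        message(sprintf("t = %6.1f s  total_M = %.4g  degraded r = %.2f um",
                        state$t, rows[[k + 1]]$total_M,
                        rows[[k + 1]]$equivalent_radius_um))
    }
  }
  structure(list(summary = do.call(rbind, rows), snapshots = snaps,
                 dt_s = dt, scenario = scenario, config = config,
                 threshold_fraction = threshold_fraction),
            class = "mmp_run")
}

#' @export
print.mmp_run <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf("mmp_run '%s': %d snapshots to t = %g min, dt = %g s\n",
              x$scenario$id, n, x$summary$t_min[n], x$dt_s))
  cat(sprintf("  final degraded equivalent radius: %.2f um; min E: %.4g\n",
              x$summary$equivalent_radius_um[n], x$summary$min_E[n]))
  invisible(x)
}

#' Extract a snapshot at a given time
#' @param run an `mmp_run` with kept fields.
#' @param t_min time in minutes (must equal a snapshot time).
#' @return a `field_state`.
#' @export
snapshot_at <- function(run, t_min) {
  if (is.null(run$snapshots)) stop("run was executed with keep_fields = FALSE")
  k <- which(abs(run$summary$t_min - t_min) < 1e-9)
  if (length(k) != 1) stop("no snapshot at t = ", t_min, " min")
  run$snapshots[[k]]
}
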