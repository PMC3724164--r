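#' Kinetic parameters of the MMP-ECM degradation system
#'
#' Bundles the rate and diffusion constants of the soluble-MMP
#' reaction-diffusion model
#' \deqn{\partial M/\partial t = \nabla\cdot(D\,\nabla M) + s - r_M E M - d_M M,
#'       \qquad \partial E/\partial t = -r_E E M,}
#' with \eqn{D = D_0 (1 - E)}, together with the initial ECM volume fraction
#' and the Dirichlet MMP value imposed on secreting cells. Defaults are the
#' standard literature values for soluble MMPs: \eqn{D_0 = 8\times 10^{-9}}
#' cm\eqn{^2}/s, \eqn{r_M = r_E = 1/200} s\eqn{^{-1}},
#' \eqn{d_M = 5\times 10^{-5}} s\eqn{^{-1}}, \eqn{E_{init} = 0.85},
#' \eqn{M = 1} on secreting cells.
#'
#' @param D0 free diffusivity of the MMP (in `D0_units`). Stored internally
#'   in um^2/s (default 8e-9 cm^2/s = 0.8 um^2/s).
#' @param D0_units `"cm2_per_s"` (default) or `"um2_per_s"`.
#' @param rM MMP consumption rate coefficient, 1/s.
#' @param rE ECM degradation rate coefficient, 1/s.
#' @param dM MMP decay rate, 1/s.
#' @param E_init initial ECM volume fraction in degradable stroma,
#'   dimensionless in \[0, 1).
#' @param M_boundary Dirichlet MMP concentration on secreting cells,
#'   dimensionless.
#' @param source_s volumetric MMP source term s(X, t), 1/s. Retained in the
#'   model but zero by default: secretion is modeled by the Dirichlet
#'   condition M = `M_boundary` on secreting cells.
#' @return an object of class `kinetic_params` (a list; `$D0` is in um^2/s).
#' @examples
#' p <- kinetic_params()
#' p$D0             # 0.8 um^2/s
#' length_scale(0.85, p)
#' @export
kinetic_params <- function(D0 = 8e-9, D0_units = "cm2_per_s",
                           rM = 1 / 200, rE = 1 / 200, dM = 5e-5,
                           E_init = 0.85, M_boundary = 1, source_s = 0) {
  D0_um2 <- convert_diffusivity(D0, from = D0_units, to = "um2_per_s")
  if (!is.numeric(D0_um2) || D0_um2 < 0) stop("D0 must be >= 0")
  if (!is.numeric(rM) || rM < 0) stop("rM must be >= 0")
  if (!is.numeric(rE) || rE < 0) stop("rE must be >= 0")
  if (!is.numeric(dM) || dM < 0) stop("dM must be >= 0")
  if (!is.numeric(E_init) || E_init < 0 || E_init >= 1)
    stop("E_init must lie in [0, 1)")
  if (!is.numeric(M_boundary) || M_boundary < 0) stop("M_boundary must be >= 0")
  structure(
    list(D0 = D0_um2, rM = rM, rE = rE, dM = dM,
         E_init = E_init, M_boundary = M_boundary, source_s = source_s),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("MMP-ECM kinetic parameters\n")
  cat(sprintf("  D0 = %g um^2/s  (%.3g cm^2/s)\n", x$D0, x$D0 / 1e8))
  cat(sprintf("  rM = %g /s, rE = %g /s, dM = %g /s\n", x$rM, x$rE, x$dM))
  cat(sprintf("  E_init = %g, M_boundary = %g\n", x$E_init, x$M_boundary))
  invisible(x)
}

.check_E <- function(E) {
  if (any(!is.finite(E)) || any(E < 0) || any(E > 1))
    stop("ECM volume fraction E must lie in [0, 1]")
  invisible(E)
}

#' ECM-dependent MMP diffusivity
#'
#' The diffusivity is reduced linearly by matrix occlusion:
#' \eqn{D(E) = D_0 (1 - E)}, vanishing in fully dense matrix.
#'
#' @param E ECM volume fraction(s) in \[0, 1\].
#' @param params a [kinetic_params()] object.
#' @return diffusivity in um^2/s (vectorized over `E`).
#' @export
diffusivity <- function(E, params = kinetic_params()) {
  .check_E(E)
  params$D0 * (1 - E)
}

#' Reaction-diffusion length scale
#'
#' Distance over which a diffusing, consumed MMP decays to 1/e of its
#' boundary value at steady state:
#' \eqn{L(E) = \sqrt{D_0(1-E) / (r_M E + d_M)}}. For the default parameters
#' L is about 5 um in dense stroma (E = 0.85) and at most ~126 um in matrix-free
#' tissue -- far shorter than typical oxygen diffusion scales, as expected for
#' a large macromolecule consumed by its substrate.
#'
#' @inheritParams diffusivity
#' @return length in um (vectorized over `E`).
#' @export
length_scale <- function(E, params = kinetic_params()) {
  .check_E(E)
  denom <- params$rM * E + params$dM
  if (any(denom <= 0))
    stop("length scale undefined: rM*E + dM must be > 0")
  sqrt(params$D0 * (1 - E) / denom)
}

#' Fisher-Kolmogorov front-speed estimate for the degradation front
#'
#' Order-of-magnitude estimate of the speed at which the MMP/degradation
#' front invades ECM, in the Fisher-Kolmogorov traveling-wave form
#' \eqn{\nu(E) = 2 L(E)\, r_M E} (the `"exact"` form, with L(E) the
#' reaction-diffusion length scale), or the simplified
#' \eqn{\nu(E) \approx 2\sqrt{D_0 (1-E)\, r_M E}} (`"approximate"`, obtained
#' by neglecting the decay rate \eqn{d_M} in L). Both vanish at E = 0 (no
#' substrate reaction) and E = 1 (no diffusion).
#'
#' @inheritParams diffusivity
#' @param form `"exact"` or `"approximate"`.
#' @return front speed in um/min (vectorized over `E`).
#' @examples
#' front_speed_estimate(0.5)    # ~3.76 um/min, the maximum over E
#' front_speed_estimate(0.85)   # ~2.69 um/min
#' @export
front_speed_estimate <- function(E, params = kinetic_params(),
                                 form = c("exact", "approximate")) {
  form <- match.arg(form)
  .check_E(E)
  v_um_s <- if (form == "exact") {
    2 * length_scale(E, params) * params$rM * E
  } else {
    2 * sqrt(params$D0 * (1 - E) * params$rM * E)
  }
  v_um_s * 60
}

#' Maximum front speed over a range of ECM fractions
#'
#' Maximizes [front_speed_estimate()] (exact form) over E in
#' \[`E_lo`, `E_hi`\] by a dense grid scan followed by golden-section
#' refinement of the bracketing interval.
#'
#' @param E_lo,E_hi range of ECM volume fractions, 0 <= E_lo <= E_hi <= 1.
#' @param params a [kinetic_params()] object.
#' @param step grid-scan resolution in E (default 1e-3).
#' @return a list with `E_at_max` and `speed` (um/min).
#' @export
max_front_speed <- function(E_lo = 0, E_hi = 0.90, params = kinetic_params(),
                            step = 1e-3) {
  if (!(E_lo >= 0 && E_hi <= 1 && E_lo <= E_hi))
    stop("require 0 <= E_lo <= E_hi <= 1")
  grid <- unique(c(seq(E_lo, E_hi, by = step), E_hi))
  v <- front_speed_estimate(grid, params, form = "exact")
  k <- which.max(v)
  E_best <- grid[k]
  v_best <- v[k]
  lo <- max(E_lo, E_best - step)
  hi <- min(E_hi, E_best + step)
  if (hi > lo) {
    opt <- optimize(function(e) front_speed_estimate(e, params, "exact"),
                    interval = c(lo, hi), maximum = TRUE,
                    tol = .Machine$double.eps^0.5)
    if (opt$objective > v_best) {
      E_best <- opt$maximum
      v_best <- opt$objective
    }
  }
  list(E_at_max = E_best, speed = v_best)
}

#' Time for a front to traverse a distance
#'
#' Long-time extrapolation helper: how long a front moving at constant speed
#' takes to cross a tissue. Used to contrast degradation-front speeds
#' (~1 um/min) with observed tumor expansion (~80-100 um/day): at 100 um/day
#' a 5 cm radius takes 500 days, while at 1 um/min it takes about a month.
#'
#' @param distance_um distance to traverse, um (>= 0).
#' @param speed front speed, um per `speed_time_unit` (> 0).
#' @param speed_time_unit time unit of `speed`: `"s"`, `"min"`, `"hour"`,
#'   `"day"`.
#' @param out_unit unit of the returned time (default: same as the speed's).
#' @return traversal time in `out_unit`; `Inf` with a warning when speed = 0.
#' @examples
#' traversal_time(5e4, 100, "day")         # 500 days
#' traversal_time(5e4, 1, "min", "day")    # ~34.7 days
#' @export
traversal_time <- function(distance_um, speed, speed_time_unit = "min",
                           out_unit = speed_time_unit) {
  if (distance_um < 0) stop("distance_um must be >= 0")
  if (speed < 0) stop("speed must be >= 0")
  if (speed == 0) {
    warning("speed is zero: traversal time is unbounded")
    return(Inf)
  }
  convert_time(distance_um / speed, from = speed_time_unit, to = out_unit)
}

#' Analytic sweep table over ECM fractions
#'
#' Tabulates diffusivity, length scale, and front-speed estimate on a grid
#' of ECM fractions; the table behind the `scales` CLI subcommand.
#'
#' @param E numeric vector of ECM fractions.
#' @param params a [kinetic_params()] object.
#' @return a data.frame with columns `E`, `D_um2_per_s`, `L_um`,
#'   `nu_um_per_min`.
#' @export
scales_table <- function(E = seq(0, 0.95, by = 0.05),
                         params = kinetic_params()) {
  data.frame(
    E = E,
    D_um2_per_s = diffusivity(E, params),
    L_um = length_scale(E, params),
    nu_um_per_min = front_speed_estimate(E, params, "exact")
  )
}
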