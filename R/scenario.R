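# Synthetic tissue scenarios: grid, embedded interfaces, initial fields.

#' Node-centered Cartesian grid specification
#'
#' Node (i, j) (0-based) sits at `origin + (i*h, j*h)`; the physical extent
#' is `(nx*h, ny*h)`. `ny = 1` gives a one-dimensional column.
#'
#' @param h mesh spacing, um (> 0).
#' @param nx,ny node counts per axis (nx >= 3, ny >= 1).
#' @param origin coordinates of node (0, 0), um.
#' @return a `grid_spec` object with precomputed node coordinates `$x`, `$y`.
#' @export
grid_spec <- function(h, nx, ny = 1, origin = c(0, 0)) {
  if (!is.finite(h) || h <= 0) stop("h must be > 0")
  if (nx < 3) stop("nx must be >= 3")
  if (ny < 1) stop("ny must be >= 1")
  structure(list(h = h, nx = as.integer(nx), ny = as.integer(ny),
                 origin = as.numeric(origin),
                 x = origin[1] + (seq_len(nx) - 1) * h,
                 y = origin[2] + (seq_len(ny) - 1) * h),
            class = "grid_spec")
}

#' Embedded interface specification
#'
#' An interface is one or more analytic shapes (union) with a biological
#' role that fixes its boundary condition: secreting cells impose a
#' Dirichlet MMP value on their boundary; basement membrane and inert
#' (non-secreting) cells are zero-flux (Neumann) obstacles.
#'
#' @param shapes a shape or list of shapes ([shape_circle()], [shape_line()]).
#' @param role `"secreting_cell"`, `"inert_cell"`, or `"basement_membrane"`.
#' @param bc_value Dirichlet MMP concentration (secreting cells only).
#' @param label optional label used in error messages.
#' @export
interface_spec <- function(shapes,
                           role = c("secreting_cell", "inert_cell",
                                    "basement_membrane"),
                           bc_value = 1, label = NULL) {
  role <- match.arg(role)
  if (inherits(shapes, "mmp_shape")) shapes <- list(shapes)
  if (length(shapes) == 0) stop("interface needs at least one shape")
  bc_kind <- if (role == "secreting_cell") "dirichlet" else "zero_flux"
  if (role != "secreting_cell" && !missing(bc_value) && bc_value != 0)
    stop("bc_value only applies to secreting cells (Dirichlet)")
  if (bc_value < 0) stop("bc_value must be >= 0")
  structure(list(shapes = shapes, role = role, bc_kind = bc_kind,
                 bc_value = bc_value,
                 label = label %||% role),
            class = "interface_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# signed distance of an interface union evaluated on the grid
.phi_on_grid <- function(interfaces, grid) {
  shapes <- unlist(lapply(interfaces, `[[`, "shapes"), recursive = FALSE)
  if (length(shapes) == 0)
    return(matrix(Inf, grid$nx, grid$ny))
  xs <- matrix(grid$x, grid$nx, grid$ny)
  ys <- matrix(rep(grid$y, each = grid$nx), grid$nx, grid$ny)
  matrix(signed_distance(shapes, as.vector(xs), as.vector(ys)),
         grid$nx, grid$ny)
}

.check_in_domain <- function(itf, grid) {
  xmax <- grid$origin[1] + (grid$nx - 1) * grid$h
  ymax <- grid$origin[2] + (grid$ny - 1) * grid$h
  for (s in itf$shapes) {
    ok <- if (s$type == "circle") {
      s$center[1] - s$radius >= grid$origin[1] &&
        s$center[1] + s$radius <= xmax &&
        (grid$ny == 1 ||
           (s$center[2] - s$radius >= grid$origin[2] &&
              s$center[2] + s$radius <= ymax))
    } else TRUE
    if (!ok)
      stop("interface '", itf$label, "' extends outside the domain [",
           grid$origin[1], ", ", xmax, "] x [", grid$origin[2], ", ", ymax,
           "] um")
  }
  invisible(TRUE)
}

.check_no_overlap <- function(interfaces) {
  # secreting and inert cells may not overlap one another
  cells <- Filter(function(i) i$role != "basement_membrane", interfaces)
  circ <- list()
  for (itf in cells)
    for (s in itf$shapes)
      if (s$type == "circle")
        circ[[length(circ) + 1]] <- list(s = s, label = itf$label)
  if (length(circ) < 2) return(invisible(TRUE))
  for (a in seq_len(length(circ) - 1)) {
    for (b in seq(a + 1, length(circ))) {
      d <- sqrt(sum((circ[[a]]$s$center - circ[[b]]$s$center)^2))
      if (d < circ[[a]]$s$radius + circ[[b]]$s$radius)
        stop("interfaces '", circ[[a]]$label, "' and '", circ[[b]]$label,
             "' overlap")
    }
  }
  invisible(TRUE)
}

#' Assemble a simulation scenario
#'
#' Combines a grid, embedded interfaces, and kinetic parameters into a
#' validated scenario: per-role level sets (signed distance on the grid),
#' node classification masks, and initial M and E fields. Degradable stroma
#' starts at `params$E_init`; lumen and cell interiors carry E = 0; nodes
#' inside secreting cells carry M = `bc_value`, all other nodes M = 0
#' (unless fields are supplied explicitly).
#'
#' @param grid a [grid_spec()].
#' @param interfaces list of [interface_spec()] objects.
#' @param params a [kinetic_params()].
#' @param initial_M,initial_E optional nx-by-ny matrices overriding the
#'   default initial fields.
#' @param freeze_E if TRUE the solver holds E fixed (validation runs).
#' @param id scenario identifier string.
#' @return an object of class `scenario`.
#' @export
new_scenario <- function(grid, interfaces, params = kinetic_params(),
                         initial_M = NULL, initial_E = NULL,
                         freeze_E = FALSE, id = "scenario") {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "kinetic_params"))
  for (itf in interfaces) {
    stopifnot(inherits(itf, "interface_spec"))
    .check_in_domain(itf, grid)
  }
  .check_no_overlap(interfaces)

  roles <- vapply(interfaces, `[[`, "", "role")
  phi_secreting <- .phi_on_grid(interfaces[roles == "secreting_cell"], grid)
  phi_inert <- .phi_on_grid(interfaces[roles == "inert_cell"], grid)
  phi_bm <- .phi_on_grid(interfaces[roles == "basement_membrane"], grid)

  sec_vals <- vapply(interfaces[roles == "secreting_cell"], `[[`, 0,
                     "bc_value")
  if (length(unique(sec_vals)) > 1)
    stop("all secreting cells must share one bc_value in this release")
  M_boundary <- if (length(sec_vals)) sec_vals[1] else params$M_boundary
  params$M_boundary <- M_boundary

  inside_secreting <- phi_secreting <= 0
  inside_inert <- phi_inert <= 0
  outside_bm <- phi_bm > 0
  active <- !inside_secreting & !inside_inert
  stroma <- active & outside_bm
  # degraded-area bookkeeping: secreting interiors count as already-degraded
  # matrix; inert cells and the lumen are excluded from metrics entirely
  metric_mask <- outside_bm & !inside_inert

  if (is.null(initial_E)) {
    initial_E <- matrix(0, grid$nx, grid$ny)
    initial_E[stroma] <- params$E_init
  }
  if (is.null(initial_M)) {
    initial_M <- matrix(0, grid$nx, grid$ny)
    initial_M[inside_secreting] <- M_boundary
  }
  stopifnot(all(dim(initial_M) == c(grid$nx, grid$ny)),
            all(dim(initial_E) == c(grid$nx, grid$ny)))
  if (any(initial_M < 0)) stop("initial_M must be >= 0 everywhere")
  if (any(initial_E < 0 | initial_E > 1))
    stop("initial_E must lie in [0, 1] everywhere")
  if (any(phi_secreting < 0 & initial_M != M_boundary))
    stop("nodes strictly inside a secreting cell must carry initial_M = bc_value")

  structure(list(
    grid = grid, interfaces = interfaces, params = params,
    phi_secreting = phi_secreting, phi_inert = phi_inert, phi_bm = phi_bm,
    inside_secreting = inside_secreting, inside_inert = inside_inert,
    outside_bm = outside_bm, active = active, stroma = stroma,
    metric_mask = metric_mask,
    initial_M = initial_M, initial_E = initial_E,
    freeze_E = isTRUE(freeze_E), id = id
  ), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  g <- x$grid
  cat(sprintf("scenario '%s': %d x %d nodes, h = %g um (%g x %g um)\n",
              x$id, g$nx, g$ny, g$h, (g$nx - 1) * g$h, (g$ny - 1) * g$h))
  cat(sprintf("  interfaces: %d (%s)\n", length(x$interfaces),
              paste(vapply(x$interfaces, `[[`, "", "role"), collapse = ", ")))
  cat(sprintf("  stroma nodes: %d, E_init = %g, freeze_E = %s\n",
              sum(x$stroma), x$params$E_init, x$freeze_E))
  invisible(x)
}

#' Ductal cross-section scenario (lumen, tumor cells, BM, stromal secretors)
#'
#' Builds the canonical invasion geometry: a circular basement membrane
#' enclosing a lumen lined with inert tumor cells, surrounded by degradable
#' stroma at `params$E_init`, with MMP-secreting stromal cells (held at
#' M = `M_boundary`) whose boundaries sit a fixed offset outside the BM
#' (default 10 um).
#'
#' @param h mesh spacing, um.
#' @param domain_um domain extent `c(width, height)`, um.
#' @param bm_center,bm_radius_um BM circle center and radius, um.
#' @param tumor_cell_radius_um radius of the inert tumor cells, um.
#' @param n_tumor_cells number of tumor cells tiling the inside of the BM
#'   (default: as many non-overlapping cells as fit on the inner ring).
#' @param stromal_cell_radius_um radius of the secreting stromal cells, um.
#' @param stromal_angles_deg angular positions of the stromal cells around
#'   the BM (degrees, measured from the +x axis).
#' @param stromal_offset_um gap between each stromal-cell boundary and the
#'   BM, measured along the connecting ray (default 10 um).
#' @param params a [kinetic_params()].
#' @return a `scenario`.
#' @export
build_duct_scenario <- function(h = 1, domain_um = c(150, 300),
                                   bm_center = c(75, 150), bm_radius_um = 40,
                                   tumor_cell_radius_um = 5,
                                   n_tumor_cells = NULL,
                                   stromal_cell_radius_um = 5,
                                   stromal_angles_deg = c(70, 90, 110),
                                   stromal_offset_um = 10,
                                   params = kinetic_params()) {
  stopifnot(bm_radius_um > 0, tumor_cell_radius_um > 0,
            stromal_cell_radius_um > 0, stromal_offset_um > 0)
  grid <- grid_spec(h, nx = round(domain_um[1] / h) + 1,
                    ny = round(domain_um[2] / h) + 1)
  interfaces <- list(interface_spec(shape_circle(bm_center, bm_radius_um),
                                    role = "basement_membrane", bc_value = 0,
                                    label = "BM"))

  # inert tumor cells on a ring just inside the BM, around a central lumen
  ring_r <- bm_radius_um - tumor_cell_radius_um - 2
  if (ring_r <= 0) stop("tumor cells do not fit inside the BM")
  n_max <- floor(pi / asin(min(1, (tumor_cell_radius_um + 0.5) / ring_r)))
  n_tum <- if (is.null(n_tumor_cells)) n_max else n_tumor_cells
  if (n_tum > n_max)
    stop("tumor cells overlap: at most ", n_max, " cells of radius ",
         tumor_cell_radius_um, " um fit on the ring")
  if (n_tum > 0) {
    ang <- 2 * pi * (seq_len(n_tum) - 1) / n_tum
    tum <- lapply(seq_len(n_tum), function(k) {
      shape_circle(bm_center + ring_r * c(cos(ang[k]), sin(ang[k])),
                   tumor_cell_radius_um)
    })
    interfaces <- c(interfaces,
                    list(interface_spec(tum, role = "inert_cell",
                                        bc_value = 0, label = "tumor cells")))
  }

  # secreting stromal cells at the configured offset outside the BM
  if (length(stromal_angles_deg) > 0) {
    cen_r <- bm_radius_um + stromal_offset_um + stromal_cell_radius_um
    for (k in seq_along(stromal_angles_deg)) {
      a <- stromal_angles_deg[k] * pi / 180
      interfaces <- c(interfaces, list(interface_spec(
        shape_circle(bm_center + cen_r * c(cos(a), sin(a)),
                     stromal_cell_radius_um),
        role = "secreting_cell", bc_value = params$M_boundary,
        label = paste0("stromal cell ", k))))
    }
  }
  new_scenario(grid, interfaces, params, id = "duct")
}

#' Single secreting-source scenario
#'
#' Minimal radial geometry isolating the hole-expansion measurement: one
#' Dirichlet disc held at M = `M_boundary` in uniform degradable stroma, no
#' basement membrane, no inert cells. The disc interior carries E = 0 and
#' counts as already-degraded matrix, so the degraded-region equivalent
#' radius starts at the disc radius.
#'
#' @param h mesh spacing, um.
#' @param domain_um domain extent `c(width, height)`, um.
#' @param disc_radius_um secreting-disc radius, um (default 5).
#' @param disc_center disc center, um (default: domain center).
#' @param params a [kinetic_params()].
#' @return a `scenario`.
#' @export
build_single_source_scenario <- function(h = 1, domain_um = c(200, 200),
                                         disc_radius_um = 5,
                                         disc_center = NULL,
                                         params = kinetic_params()) {
  grid <- grid_spec(h, nx = round(domain_um[1] / h) + 1,
                    ny = round(domain_um[2] / h) + 1)
  if (is.null(disc_center))
    disc_center <- c((grid$nx - 1) * h / 2, (grid$ny - 1) * h / 2)
  itf <- interface_spec(shape_circle(disc_center, disc_radius_um),
                        role = "secreting_cell",
                        bc_value = params$M_boundary, label = "source disc")
  new_scenario(grid, list(itf), params, id = "single_source")
}

#' One-dimensional validation column
#'
#' A 1-D column with a Dirichlet MMP source at the left boundary
#' (M = `M_boundary` for x <= `boundary_at_um`) and zero-flux right
#' boundary, used to compare steady states against the analytic
#' exp(-x / L(E)) profile. With `freeze_E = TRUE` the matrix is held fixed
#' and the linear steady state applies exactly.
#'
#' @param length_um column length, um.
#' @param h mesh spacing, um.
#' @param E_init ECM fraction of the column (default `params$E_init`).
#' @param freeze_E hold E fixed (default TRUE).
#' @param boundary_at_um position of the source line (default 0: the first
#'   node is held at `M_boundary`).
#' @param params a [kinetic_params()].
#' @return a `scenario` with `ny = 1`. Warns when the column is shorter than
#'   10 L(E_init), where truncation pollutes the exponential tail.
#' @export
build_1d_column_scenario <- function(length_um = 100, h = 1, E_init = NULL,
                                     freeze_E = TRUE, boundary_at_um = 0,
                                     params = kinetic_params()) {
  if (!is.null(E_init)) params$E_init <- E_init
  grid <- grid_spec(h, nx = round(length_um / h) + 1, ny = 1)
  L <- length_scale(params$E_init, params)
  if (is.finite(L) && L > 0 && length_um < 10 * L)
    warning(sprintf(paste("column length %g um < 10 L(E_init) = %g um:",
                          "domain truncation will pollute the exponential",
                          "tail"), length_um, 10 * L))
  itf <- interface_spec(shape_line("x", boundary_at_um, inside = "below"),
                        role = "secreting_cell",
                        bc_value = params$M_boundary, label = "source plane")
  new_scenario(grid, list(itf), params, freeze_E = freeze_E,
               id = "column_1d")
}
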