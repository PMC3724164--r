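# Analytic shapes and signed-distance functions. Sign convention (used
# everywhere in the package): negative inside a cell / on the non-diffusing
# side of an interface, positive in diffusing tissue.

#' Analytic circle shape
#'
#' @param center numeric length-2, center coordinates in um.
#' @param radius circle radius in um (> 0).
#' @return a shape object usable in [interface_spec()] and
#'   [signed_distance()].
#' @export
shape_circle <- function(center, radius) {
  if (length(center) != 2 || !all(is.finite(center)))
    stop("center must be two finite coordinates (um)")
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  structure(list(type = "circle", center = as.numeric(center),
                 radius = radius), class = "mmp_shape")
}

#' Axis-aligned line (half-plane) shape
#'
#' The interface is the line `axis = at`; `inside` selects which half-plane
#' is the interior (negative signed distance).
#'
#' @param axis `"x"` or `"y"` -- the coordinate the line fixes.
#' @param at position of the line along that coordinate, um.
#' @param inside `"below"` (coordinate <= at is interior, default) or
#'   `"above"`.
#' @export
shape_line <- function(axis = c("x", "y"), at, inside = c("below", "above")) {
  axis <- match.arg(axis)
  inside <- match.arg(inside)
  if (!is.finite(at)) stop("line position must be finite")
  structure(list(type = "line", axis = axis, at = at, inside = inside),
            class = "mmp_shape")
}

.shape_sd <- function(shape, x, y) {
  switch(shape$type,
    circle = sqrt((x - shape$center[1])^2 + (y - shape$center[2])^2) -
      shape$radius,
    line = {
      coord <- if (shape$axis == "x") x else y
      if (shape$inside == "below") coord - shape$at else shape$at - coord
    },
    stop("unknown shape type: ", shape$type)
  )
}

#' Signed distance to a set of shapes
#'
#' Exact signed distance for single circles and axis-aligned lines; for a
#' union of shapes, the pointwise minimum of the member signed distances
#' (negative inside any member).
#'
#' @param shapes a single shape or a list of shapes from [shape_circle()] /
#'   [shape_line()].
#' @param x,y point coordinates in um (vectorized).
#' @return signed distance(s) in um; negative inside.
#' @examples
#' signed_distance(shape_circle(c(0, 0), 5), 3, 4)   # 0, on the circle
#' signed_distance(shape_circle(c(0, 0), 5), 6, 8)   # +5
#' @export
signed_distance <- function(shapes, x, y) {
  if (inherits(shapes, "mmp_shape")) shapes <- list(shapes)
  if (length(shapes) == 0) stop("shape set must be nonempty")
  d <- .shape_sd(shapes[[1]], x, y)
  for (s in shapes[-1]) d <- pmin(d, .shape_sd(s, x, y))
  d
}
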