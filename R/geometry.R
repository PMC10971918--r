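#' Elliptical primitive
#'
#' Defines a (possibly tilted) ellipse in head coordinates: origin at the
#' centre of the electrode belt, x to the right, y up, millimetre units.
#'
#' @param center_x,center_y Centre position in mm.
#' @param semi_a Semiaxis along the local x direction, mm (> 0).
#' @param semi_b Semiaxis along the local y direction, mm (> 0).
#' @param tilt Counter-clockwise rotation about the centre, degrees, in
#'   (-180, 180].
#' @return An object of class `ellipse_spec`.
#' @seealso [half_plane_spec()], [region_union()], [point_in_region()]
#' @export
#' @examples
#' e <- ellipse_spec(0, 0, 77, 105, 0)
#' ellipse_perimeter(e$semi_a, e$semi_b)
ellipse_spec <- function(center_x, center_y, semi_a, semi_b, tilt = 0) {
  stopifnot(is.numeric(center_x), is.numeric(center_y),
            is.numeric(semi_a), is.numeric(semi_b), is.numeric(tilt))
  if (!is.finite(semi_a) || !is.finite(semi_b) || semi_a <= 0 || semi_b <= 0)
    stop("ellipse semiaxes must be positive and finite")
  tilt <- wrap_angle(tilt)
  structure(list(center_x = center_x, center_y = center_y,
                 semi_a = semi_a, semi_b = semi_b, tilt = tilt),
            class = c("ellipse_spec", "region_expr"))
}

#' Half-plane primitive
#'
#' A half plane bounded by a line through `(anchor_x, anchor_y)` tilted by
#' `tilt` degrees from the vertical axis (positive tilt leans the line
#' counter-clockwise). The head phantom uses one such line to divide the
#' brain into left and right hemispheres.
#'
#' @param anchor_x,anchor_y A point on the dividing line, mm.
#' @param tilt Line tilt relative to the vertical axis, degrees.
#' @param side Which side of the line belongs to the region, `"left"` or
#'   `"right"` (as seen looking up the line direction).
#' @return An object of class `half_plane_spec`.
#' @export
half_plane_spec <- function(anchor_x, anchor_y, tilt = 0,
                            side = c("left", "right")) {
  side <- match.arg(side)
  structure(list(anchor_x = anchor_x, anchor_y = anchor_y,
                 tilt = wrap_angle(tilt), side = side),
            class = c("half_plane_spec", "region_expr"))
}

wrap_angle <- function(deg) {
  a <- (deg + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

#' Boolean region algebra
#'
#' Combine geometric primitives (or already combined regions) into a region
#' expression supporting point-membership queries and rasterization.
#' `region_diff(a, b)` is the set difference a minus b.
#'
#' @param a,b Objects of class `region_expr` (primitives or combinations).
#' @return An object of class `region_expr`.
#' @export
region_union <- function(a, b) region_node("union", a, b)

#' @rdname region_union
#' @export
region_intersect <- function(a, b) region_node("intersection", a, b)

#' @rdname region_union
#' @export
region_diff <- function(a, b) region_node("difference", a, b)

region_node <- function(op, a, b) {
  stopifnot(inherits(a, "region_expr"), inherits(b, "region_expr"))
  structure(list(op = op, a = a, b = b),
            class = c("region_node", "region_expr"))
}

#' Point membership of a region expression
#'
#' Evaluates the region predicate at the given coordinates (vectorized).
#' Ellipse membership uses the tilted-ellipse quadratic form; points on the
#' boundary count as inside.
#'
#' @param expr A `region_expr`.
#' @param x,y Coordinates in mm (equal-length numeric vectors).
#' @return Logical vector of memberships.
#' @export
point_in_region <- function(expr, x, y) {
  stopifnot(inherits(expr, "region_expr"), length(x) == length(y))
  if (inherits(expr, "ellipse_spec")) {
    th <- expr$tilt * pi / 180
    dx <- x - expr$center_x
    dy <- y - expr$center_y
    u <-  cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    return((u / expr$semi_a)^2 + (v / expr$semi_b)^2 <= 1)
  }
  if (inherits(expr, "half_plane_spec")) {
    th <- expr$tilt * pi / 180
    # line direction (pointing "up" the tilted vertical)
    s <- (x - expr$anchor_x) * cos(th) - (y - expr$anchor_y) * (-sin(th))
    return(if (expr$side == "left") s <= 0 else s >= 0)
  }
  a <- point_in_region(expr$a, x, y)
  b <- point_in_region(expr$b, x, y)
  switch(expr$op,
         union = a | b,
         intersection = a & b,
         difference = a & !b)
}

#' Square raster grid
#'
#' A square pixel grid centred on the origin, used both for phantom property
#' maps and for the finite-volume solver. Pixel centres are returned in mm.
#'
#' @param extent_mm Side length of the square field of view, mm.
#' @param n Number of pixels per side (>= 8).
#' @return An object of class `raster_grid` with pixel-centre coordinate
#'   vectors `x`, `y` (length `n`, x increasing, y increasing), pixel size
#'   `h`, and full centre matrices accessible via [grid_points()].
#' @export
raster_grid <- function(extent_mm, n) {
  stopifnot(extent_mm > 0, n >= 8)
  h <- extent_mm / n
  cc <- (seq_len(n) - (n + 1) / 2) * h
  structure(list(extent = extent_mm, n = as.integer(n), h = h, x = cc, y = cc),
            class = "raster_grid")
}

#' @rdname raster_grid
#' @param grid A `raster_grid`.
#' @return `grid_points()` returns a list with vectors `x` and `y` of length
#'   `n^2` giving all pixel centres in column-major order (x varies fastest
#'   down matrix rows; element `[i, j]` of a raster matrix corresponds to
#'   `x[i]`, `y[j]`).
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  list(x = rep(grid$x, times = grid$n), y = rep(grid$y, each = grid$n))
}

#' Rasterize a region expression
#'
#' Pixel-centre sampling of the membership predicate on a square grid. The
#' mask area times pixel area converges to the true region area as the
#' resolution grows.
#'
#' @param expr A `region_expr`.
#' @param grid A [raster_grid()].
#' @return An `n x n` logical matrix; element `[i, j]` is the pixel centred
#'   at `(grid$x[i], grid$y[j])` so the matrix x-axis runs down rows.
#' @export
rasterize <- function(expr, grid) {
  stopifnot(inherits(grid, "raster_grid"))
  p <- grid_points(grid)
  matrix(point_in_region(expr, p$x, p$y), nrow = grid$n, ncol = grid$n)
}

#' Exact ellipse perimeter
#'
#' Arc length of an ellipse with the given semiaxes, via the complete
#' elliptic integral of the second kind. Used to enforce the circumference
#' constraints of the phantom constraint tables; the head outline with
#' semiaxes 77 and 105 mm has a perimeter of 575 mm, the assumed average
#' head circumference.
#'
#' @param semi_a,semi_b Semiaxes in mm (> 0). The function is symmetric in
#'   its arguments.
#' @return Perimeter in mm, accurate to well below 0.01 mm.
#' @export
#' @examples
#' round(ellipse_perimeter(105, 77)) # 575
ellipse_perimeter <- function(semi_a, semi_b) {
  if (!all(is.finite(c(semi_a, semi_b))) || any(semi_a <= 0) || any(semi_b <= 0))
    stop("semiaxes must be positive")
  a <- pmax(semi_a, semi_b)
  b <- pmin(semi_a, semi_b)
  m <- 1 - (b / a)^2  # elliptic parameter m = e^2
  # pracma::ellipke computes E(m) with the m convention
  e <- vapply(m, function(mi) pracma::ellipke(mi)$e, numeric(1))
  4 * a * e
}
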