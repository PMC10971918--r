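# Constrained sampling of phantom geometry parameters and their resolution
# into absolute ellipse specifications.

ELEMENT_FIELDS <- c("center_x", "center_y", "size_x", "size_y", "tilt")
SATELLITE_FIELDS <- c("axis_angle", "shift", "size_x", "size_y", "tilt")

draw_element_params <- function(spec, fields, law) {
  vapply(fields, function(f) {
    r <- spec[[f]]
    draw_ranged(1, r$mean, r$hr, law)
  }, numeric(1))
}

mean_element_params <- function(spec, fields) {
  vapply(fields, function(f) spec[[f]]$mean, numeric(1))
}

# Resolve a raw parameter vector for a table element into an absolute
# ellipse: centre offsets rotated into the reference's tilted frame, size
# offsets added per semiaxis, tilts added to the reference tilt.
resolve_element <- function(p, ref) {
  th <- ref$tilt * pi / 180
  cx <- ref$center_x + cos(th) * p[["center_x"]] - sin(th) * p[["center_y"]]
  cy <- ref$center_y + sin(th) * p[["center_x"]] + cos(th) * p[["center_y"]]
  sa <- ref$semi_a + p[["size_x"]]
  sb <- ref$semi_b + p[["size_y"]]
  if (sa <= 0 || sb <= 0) return(NULL)
  ellipse_spec(cx, cy, sa, sb, ref$tilt + p[["tilt"]])
}

# Satellite CSF ellipse: absolute size/tilt, positioned at an angular
# position on the parent ellipse, shifted along the outward normal there.
resolve_satellite <- function(p, parent) {
  phi <- p[["axis_angle"]] * pi / 180
  th <- parent$tilt * pi / 180
  px <- parent$semi_a * cos(phi)
  py <- parent$semi_b * sin(phi)
  nx <- cos(phi) / parent$semi_a
  ny <- sin(phi) / parent$semi_b
  nn <- sqrt(nx^2 + ny^2)
  lx <- px + p[["shift"]] * nx / nn
  ly <- py + p[["shift"]] * ny / nn
  if (p[["size_x"]] <= 0 || p[["size_y"]] <= 0) return(NULL)
  ellipse_spec(parent$center_x + cos(th) * lx - sin(th) * ly,
               parent$center_y + sin(th) * lx + cos(th) * ly,
               p[["size_x"]], p[["size_y"]], p[["tilt"]])
}

axes_ratio <- function(e) e$semi_b / e$semi_a

# Check a resolved element against its enforced circumference / axes-ratio
# constraints. `inner_perim` is needed for ratio-type entries; for lobe sum
# constraints the partner perimeter is supplied.
element_shape_ok <- function(e, spec, inner_perim = NULL, partner_perim = NULL) {
  p <- ellipse_perimeter(e$semi_a, e$semi_b)
  cc <- spec[["circumference"]]
  if (!is.null(cc) && isTRUE(cc$enforce %||% TRUE) &&
      !in_range(p, cc$mean, cc$hr)) return(FALSE)
  cr <- spec[["circumference_ratio"]]
  if (!is.null(cr) && isTRUE(cr$enforce %||% TRUE)) {
    val <- if (is.null(cr$sum_with)) p / inner_perim
           else (p + partner_perim) / inner_perim
    if (!in_range(val, cr$mean, cr$hr)) return(FALSE)
  }
  ar <- spec[["axes_ratio"]]
  if (!is.null(ar) && isTRUE(ar$enforce %||% TRUE) &&
      !in_range(axes_ratio(e), ar$mean, ar$hr)) return(FALSE)
  TRUE
}

# Resolve the full raw parameter list into absolute geometry. Returns NULL
# if any ellipse degenerates (non-positive semiaxis).
resolve_geometry <- function(params, tables) {
  h <- tables$head
  head_e <- ellipse_spec(h$center[1], h$center[2], h$semi_x, h$semi_y, h$tilt)
  el <- list()
  el$inner <- resolve_element(params$inner, head_e)
  if (is.null(el$inner)) return(NULL)
  for (nm in c("ldown", "lup", "rdown", "rup", "center_csf")) {
    el[[nm]] <- resolve_element(params[[nm]], el$inner)
    if (is.null(el[[nm]])) return(NULL)
  }
  for (nm in c("csf1", "csf2", "csf3", "csf4")) {
    el[[nm]] <- resolve_satellite(params[[nm]], el$center_csf)
    if (is.null(el[[nm]])) return(NULL)
  }
  structure(list(head = head_e, elements = el,
                 midline = params$midline,
                 skin_thickness = h$skin_thickness_mm,
                 image = tables$image, params = params),
            class = "head_geometry")
}

#' @export
print.head_geometry <- function(x, ...) {
  cat("<head_geometry> outline", x$head$semi_a, "x", x$head$semi_b, "mm;",
      length(x$elements), "elements\n")
  invisible(x)
}

#' Region expressions of a resolved geometry
#'
#' Builds the boolean region algebra of the phantom: each hemisphere is the
#' intersection of the Inner ellipse with the union of its upper and lower
#' lobe ellipses, clipped to its side of the dividing line; the CSF region is
#' the interior of Inner not occupied by brain, together with the five CSF
#' ellipses (which override brain tissue); the skin/skull annuli lie between
#' the Inner ellipse and the head outline.
#'
#' @param geom A `head_geometry` from [sample_geometry()].
#' @return Named list of `region_expr` objects: `head`, `skin`, `skull_skin`,
#'   `inner`, `left`, `right`, `csf_ellipses`.
#' @export
geometry_regions <- function(geom) {
  stopifnot(inherits(geom, "head_geometry"))
  el <- geom$elements
  m <- geom$midline
  hp_left <- half_plane_spec(m[["shift_x"]], m[["shift_y"]], m[["tilt"]], "left")
  hp_right <- half_plane_spec(m[["shift_x"]], m[["shift_y"]], m[["tilt"]], "right")
  left <- region_intersect(el$inner,
                           region_intersect(region_union(el$lup, el$ldown),
                                            hp_left))
  right <- region_intersect(el$inner,
                            region_intersect(region_union(el$rup, el$rdown),
                                             hp_right))
  csf_ell <- region_intersect(
    Reduce(region_union, list(el$center_csf, el$csf1, el$csf2, el$csf3, el$csf4)),
    el$inner)
  h <- geom$head
  skin_inner <- ellipse_spec(h$center_x, h$center_y,
                             h$semi_a - geom$skin_thickness,
                             h$semi_b - geom$skin_thickness, h$tilt)
  list(head = h, skin = region_diff(h, skin_inner), skull_skin = region_diff(h, el$inner),
       inner = el$inner, left = left, right = right, csf_ellipses = csf_ell)
}

#' Area fractions of a phantom geometry
#'
#' Rasterizes the phantom regions and measures the area statistics that
#' constrain accepted samples: brain area and skin+skull ("rest of head")
#' area as percentages of the total image area, CSF area as a percentage of
#' the head area, and the left/right hemisphere area ratio in percent.
#'
#' @param geom A `head_geometry`.
#' @param n Raster resolution used for the measurement (default from the
#'   constraint tables).
#' @return Named list: `brain_pct`, `csf_pct`, `rest_pct`, `hemi_ratio_pct`,
#'   `head_pct`.
#' @export
area_fractions <- function(geom, n = NULL) {
  stopifnot(inherits(geom, "head_geometry"))
  n <- n %||% geom$image$area_check_px %||% 128
  grid <- raster_grid(geom$image$extent_mm, n)
  reg <- geometry_regions(geom)
  p <- grid_points(grid)
  head_m <- point_in_region(reg$head, p$x, p$y)
  inner_m <- point_in_region(reg$inner, p$x, p$y)
  left_m <- point_in_region(reg$left, p$x, p$y)
  right_m <- point_in_region(reg$right, p$x, p$y)
  csf_e <- point_in_region(reg$csf_ellipses, p$x, p$y)
  left_b <- left_m & !csf_e
  right_b <- right_m & !csf_e
  brain <- left_b | right_b
  csf <- inner_m & !brain
  tot <- n * n
  list(brain_pct = 100 * sum(brain) / tot,
       csf_pct = 100 * sum(csf) / max(1, sum(head_m)),
       rest_pct = 100 * sum(head_m & !inner_m) / tot,
       hemi_ratio_pct = 100 * sum(left_b) / max(1, sum(right_b)),
       head_pct = 100 * sum(head_m) / tot)
}

# Containment: the Inner ellipse must stay inside the skull (head outline
# shrunk by the skin thickness), probed on boundary points.
containment_ok <- function(geom, n_probe = 90) {
  el <- geom$elements$inner
  t <- seq(0, 2 * pi, length.out = n_probe + 1)[-1]
  th <- el$tilt * pi / 180
  bx <- el$center_x + cos(th) * el$semi_a * cos(t) - sin(th) * el$semi_b * sin(t)
  by <- el$center_y + sin(th) * el$semi_a * cos(t) + cos(th) * el$semi_b * sin(t)
  h <- geom$head
  shrunk <- ellipse_spec(h$center_x, h$center_y,
                         h$semi_a - geom$skin_thickness,
                         h$semi_b - geom$skin_thickness, h$tilt)
  all(point_in_region(shrunk, bx, by))
}

geometry_valid <- function(geom, tables) {
  if (is.null(geom)) return("degenerate ellipse")
  if (!containment_ok(geom)) return("inner outside skull")
  ac <- tables$area_constraints
  fr <- area_fractions(geom)
  if (!in_range(fr$brain_pct, ac$brain_fraction$mean, ac$brain_fraction$hr))
    return("brain area fraction")
  if (!in_range(fr$csf_pct, ac$csf_fraction$mean, ac$csf_fraction$hr))
    return("csf area fraction")
  if (!in_range(fr$rest_pct, ac$rest_fraction$mean, ac$rest_fraction$hr))
    return("rest-of-head area fraction")
  if (!in_range(fr$hemi_ratio_pct, ac$hemisphere_ratio$mean,
                ac$hemisphere_ratio$hr))
    return("hemisphere area ratio")
  NULL
}

# Draw one element subject to its enforced circumference/axes-ratio
# constraints by local rejection.
draw_element <- function(name, tables, ref, law, local_attempts,
                         inner_perim = NULL, partner_perim = NULL,
                         satellite = FALSE) {
  spec <- if (satellite) tables$satellites[[name]] else tables$elements[[name]]
  fields <- if (satellite) SATELLITE_FIELDS else ELEMENT_FIELDS
  for (i in seq_len(local_attempts)) {
    p <- draw_element_params(spec, fields, law)
    e <- if (satellite) resolve_satellite(p, ref) else resolve_element(p, ref)
    if (is.null(e)) next
    if (element_shape_ok(e, spec, inner_perim, partner_perim))
      return(list(params = p, ellipse = e))
  }
  stop("sampling failure: element '", name,
       "' constraints unsatisfiable in ", local_attempts, " attempts")
}

#' Sample a constrained phantom geometry
#'
#' Draws every element of the head phantom from the constraint tables:
#' each parameter is drawn within its `mean +/- half-range` window (truncated
#' normal by default), per-element circumference and axes-ratio constraints
#' are honoured by local rejection, and whole geometries are rejected until
#' the global area-fraction and hemisphere-balance constraints and the
#' skull-containment requirement hold.
#'
#' @param tables Constraint tables from [load_constraint_tables()].
#' @param seed Optional integer seed; sampling is bit-reproducible under a
#'   fixed seed and leaves the caller's RNG state untouched.
#' @param law Within-range sampling law, `"truncnorm"` (default, sd equal to
#'   half the half-range) or `"uniform"`; `NULL` takes the config value.
#' @param max_attempts Global rejection budget; on exhaustion an error names
#'   the constraint that failed most often.
#' @return A `head_geometry` object.
#' @export
#' @examples
#' tab <- load_constraint_tables()
#' g <- sample_geometry(tab, seed = 1)
#' area_fractions(g)$brain_pct
sample_geometry <- function(tables, seed = NULL, law = NULL,
                            max_attempts = NULL) {
  stopifnot(inherits(tables, "cceit_constraints"))
  law <- law %||% tables$sampling$law
  max_attempts <- max_attempts %||% tables$sampling$max_attempts
  local_attempts <- tables$sampling$local_attempts
  with_local_seed(seed, {
    fails <- c()
    for (attempt in seq_len(max_attempts)) {
      params <- list()
      params$midline <- vapply(c("shift_x", "shift_y", "tilt"), function(f) {
        r <- tables$midline[[f]]
        draw_ranged(1, r$mean, r$hr, law)
      }, numeric(1))
      h <- tables$head
      head_e <- ellipse_spec(h$center[1], h$center[2], h$semi_x, h$semi_y, h$tilt)
      inner <- draw_element("inner", tables, head_e, law, local_attempts)
      params$inner <- inner$params
      ip <- ellipse_perimeter(inner$ellipse$semi_a, inner$ellipse$semi_b)
      perims <- list()
      for (nm in c("ldown", "rdown")) {
        d <- draw_element(nm, tables, inner$ellipse, law, local_attempts,
                          inner_perim = ip)
        params[[nm]] <- d$params
        perims[[nm]] <- ellipse_perimeter(d$ellipse$semi_a, d$ellipse$semi_b)
      }
      for (nm in c("lup", "rup")) {
        partner <- tables$elements[[nm]]$circumference_ratio$sum_with %||% "ldown"
        d <- draw_element(nm, tables, inner$ellipse, law, local_attempts,
                          inner_perim = ip, partner_perim = perims[[partner]])
        params[[nm]] <- d$params
      }
      ccsf <- draw_element("center_csf", tables, inner$ellipse, law,
                           local_attempts, inner_perim = ip)
      params$center_csf <- ccsf$params
      for (nm in c("csf1", "csf2", "csf3", "csf4")) {
        d <- draw_element(nm, tables, ccsf$ellipse, law, local_attempts,
                          satellite = TRUE)
        params[[nm]] <- d$params
      }
      geom <- resolve_geometry(params, tables)
      why <- geometry_valid(geom, tables)
      if (is.null(why)) {
        geom$law <- law
        return(geom)
      }
      fails <- c(fails, why)
    }
    tt <- sort(table(fails), decreasing = TRUE)
    stop("sampling failure: rejection budget (", max_attempts,
         ") exhausted; dominant violated constraint: ", names(tt)[1])
  })
}

#' Perturb an existing phantom geometry
#'
#' Second generation approach: takes an accepted geometry and adds
#' independent Gaussian noise to every raw model parameter. Noise for each
#' parameter has standard deviation `relative_sd` times that parameter's
#' constraint-table half-range (its natural scale), so a single knob
#' controls the perturbation strength. The result is re-validated against
#' the containment and area constraints and redrawn on violation.
#'
#' @param base A `head_geometry` to perturb.
#' @param tables Constraint tables (supply the same tables the base was
#'   drawn from).
#' @param relative_sd Perturbation strength relative to each parameter's
#'   half-range; default 0.05.
#' @param seed Optional integer seed.
#' @param max_attempts Rejection budget for re-validation.
#' @return A `head_geometry` object.
#' @export
perturb_geometry <- function(base, tables, relative_sd = 0.05, seed = NULL,
                             max_attempts = NULL) {
  stopifnot(inherits(base, "head_geometry"), relative_sd >= 0)
  stopifnot(inherits(tables, "cceit_constraints"))
  max_attempts <- max_attempts %||% tables$sampling$max_attempts
  if (relative_sd == 0) return(base)
  hr_of <- function(group, nm, f) {
    spec <- if (group == "midline") tables$midline[[f]]
    else if (nm %in% names(tables$elements)) tables$elements[[nm]][[f]]
    else tables$satellites[[nm]][[f]]
    spec$hr
  }
  with_local_seed(seed, {
    fails <- c()
    for (attempt in seq_len(max_attempts)) {
      params <- base$params
      for (nm in names(params)) {
        group <- if (nm == "midline") "midline" else "element"
        fs <- names(params[[nm]])
        hrs <- vapply(fs, function(f) hr_of(group, nm, f), numeric(1))
        params[[nm]] <- params[[nm]] +
          stats::rnorm(length(fs), 0, relative_sd * hrs)
      }
      geom <- resolve_geometry(params, tables)
      why <- geometry_valid(geom, tables)
      if (is.null(why)) {
        geom$law <- base$law
        return(geom)
      }
      fails <- c(fails, why)
    }
    tt <- sort(table(fails), decreasing = TRUE)
    stop("sampling failure: perturbation budget (", max_attempts,
         ") exhausted; dominant violated constraint: ", names(tt)[1])
  })
}

#' Mean (degenerate) geometry
#'
#' The geometry obtained with every half-range set to zero: each parameter
#' at its table mean. Useful as a reference phantom and for tests.
#'
#' @param tables Constraint tables.
#' @return A `head_geometry`.
#' @export
mean_geometry <- function(tables) {
  stopifnot(inherits(tables, "cceit_constraints"))
  params <- list()
  params$midline <- vapply(c("shift_x", "shift_y", "tilt"),
                           function(f) tables$midline[[f]]$mean, numeric(1))
  for (nm in names(tables$elements))
    params[[nm]] <- mean_element_params(tables$elements[[nm]], ELEMENT_FIELDS)
  for (nm in names(tables$satellites))
    params[[nm]] <- mean_element_params(tables$satellites[[nm]], SATELLITE_FIELDS)
  resolve_geometry(params, tables)
}
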