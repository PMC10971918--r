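# Head phantom assembly: dielectric property assignment, rasterized region /
# property maps, artery rays, and stroke lesion insertion.

#' Dielectric properties of head tissues at 64 MHz
#'
#' Published relative permittivity and conductivity of the individual head
#' tissues at 64 MHz (the 1.5 T Larmor frequency). These per-tissue values
#' underlie the averaged region priors of [region_priors()]; the phantom
#' itself uses the region-level values.
#'
#' @return A data.frame with columns `tissue`, `eps_r`, `sigma_mS_m`.
#' @export
tissue_table <- function() {
  data.frame(
    tissue = c("white matter", "grey matter", "bones", "csf", "fat", "skin"),
    eps_r = c(67.8, 97.4, 16.7, 97.3, 13.6, 92.2),
    sigma_mS_m = c(292, 511, 59.5, 2070, 66.2, 436)
  )
}

#' Dielectric priors of the phantom regions at 64 MHz
#'
#' Mean and standard deviation of relative permittivity and conductivity for
#' the three electrically distinct phantom regions (skull+skin, brain
#' hemispheres, CSF), as measured over 50 segmented head cross-sections.
#' Used as Gaussian priors when assigning per-phantom region properties.
#'
#' @return A data.frame with columns `region`, `eps_mean`, `eps_sd`,
#'   `sigma_mean`, `sigma_sd` (conductivities in mS/m).
#' @export
region_priors <- function() {
  data.frame(
    region = c("skull", "brain", "csf"),
    eps_mean = c(14.79, 46.46, 61.26),
    eps_sd = c(1.77, 3.44, 4.40),
    sigma_mean = c(102, 378, 788),
    sigma_sd = c(29, 59, 207)
  )
}

# Dielectric constants of the two stroke types: hemorrhagic lesions take the
# conductivity/permittivity of blood; ischemic conductivity is a uniform
# fraction of the host brain conductivity with unchanged permittivity.
STROKE_HEMORRHAGIC <- list(sigma = 1230, eps = 76)
ISCHEMIC_SIGMA_RANGE <- c(0.60, 0.70)

#' Draw per-region dielectric properties
#'
#' Gaussian draws of `(eps_r, sigma)` for the skull+skin, brain, and CSF
#' regions from the [region_priors()], redrawn until the physiological
#' ordering holds: CSF values exceed brain values and brain values exceed
#' skull+skin values, for both permittivity and conductivity.
#'
#' @param priors A data.frame in the [region_priors()] layout.
#' @param seed Optional integer seed.
#' @param max_attempts Resampling budget for the ordering constraint.
#' @return Named list `skull`, `brain`, `csf`, each `list(eps, sigma)`
#'   (sigma in mS/m).
#' @export
#' @examples
#' p <- assign_region_properties(seed = 1)
#' p$csf$sigma > p$brain$sigma
assign_region_properties <- function(priors = region_priors(), seed = NULL,
                                     max_attempts = 10000) {
  stopifnot(all(c("region", "eps_mean", "eps_sd", "sigma_mean", "sigma_sd")
                %in% names(priors)))
  rows <- split(priors, priors$region)
  with_local_seed(seed, {
    for (i in seq_len(max_attempts)) {
      vals <- lapply(rows, function(r)
        list(eps = stats::rnorm(1, r$eps_mean, r$eps_sd),
             sigma = stats::rnorm(1, r$sigma_mean, r$sigma_sd)))
      ok <- vals$csf$sigma > vals$brain$sigma &&
        vals$brain$sigma > vals$skull$sigma &&
        vals$csf$eps > vals$brain$eps &&
        vals$brain$eps > vals$skull$eps &&
        vals$skull$sigma > 0 && vals$skull$eps >= 1
      if (ok) return(vals[c("skull", "brain", "csf")])
    }
    stop("property ordering unattainable in ", max_attempts, " draws")
  })
}

# Region label codes of the phantom maps.
REGION_LEVELS <- c(outside = 0L, skin = 1L, skull = 2L, left_brain = 3L,
                   right_brain = 4L, csf = 5L, lesion = 6L)

# Compose region-label and property maps on a grid from resolved geometry,
# region property values, and an optional stroke descriptor.
compose_maps <- function(geom, props, grid, stroke = NULL) {
  reg <- geometry_regions(geom)
  p <- grid_points(grid)
  head_m <- point_in_region(reg$head, p$x, p$y)
  skin_m <- point_in_region(reg$skin, p$x, p$y)
  inner_m <- point_in_region(reg$inner, p$x, p$y)
  left_m <- point_in_region(reg$left, p$x, p$y)
  right_m <- point_in_region(reg$right, p$x, p$y)
  csf_e <- point_in_region(reg$csf_ellipses, p$x, p$y)
  lab <- integer(length(p$x))                       # outside = 0
  lab[head_m & !inner_m] <- REGION_LEVELS[["skull"]]
  lab[skin_m] <- REGION_LEVELS[["skin"]]
  lab[left_m] <- REGION_LEVELS[["left_brain"]]
  lab[right_m] <- REGION_LEVELS[["right_brain"]]
  lab[inner_m & lab %in% c(0L, REGION_LEVELS[["skull"]])] <- REGION_LEVELS[["csf"]]
  lab[csf_e] <- REGION_LEVELS[["csf"]]              # CSF overrides brain
  if (!is.null(stroke)) {
    circ <- ellipse_spec(stroke$center_x, stroke$center_y,
                         stroke$radius, stroke$radius, 0)
    in_c <- point_in_region(circ, p$x, p$y)
    hemi_lab <- if (stroke$hemisphere == "left") REGION_LEVELS[["left_brain"]]
                else REGION_LEVELS[["right_brain"]]
    lesion <- in_c & lab == hemi_lab                # CSF already subtracted
    lab[lesion] <- REGION_LEVELS[["lesion"]]
  }
  sig <- numeric(length(lab))                        # background: free space
  eps <- rep(1, length(lab))
  fill <- function(code, e, s) {
    m <- lab == code
    eps[m] <<- e; sig[m] <<- s
  }
  fill(REGION_LEVELS[["skin"]], props$skull$eps, props$skull$sigma)
  fill(REGION_LEVELS[["skull"]], props$skull$eps, props$skull$sigma)
  fill(REGION_LEVELS[["left_brain"]], props$brain$eps, props$brain$sigma)
  fill(REGION_LEVELS[["right_brain"]], props$brain$eps, props$brain$sigma)
  fill(REGION_LEVELS[["csf"]], props$csf$eps, props$csf$sigma)
  if (!is.null(stroke))
    fill(REGION_LEVELS[["lesion"]], stroke$eps_lesion, stroke$sigma_lesion)
  n <- grid$n
  list(labels = matrix(lab, n, n), sigma = matrix(sig, n, n),
       eps = matrix(eps, n, n))
}

#' Build a healthy head phantom
#'
#' Rasterizes a sampled geometry into region-label, conductivity, and
#' permittivity maps with the given per-region dielectric values. Outside
#' the head the maps hold free-space values (`eps_r = 1`, `sigma = 0`).
#'
#' @param geometry A `head_geometry` from [sample_geometry()].
#' @param properties Region property list from [assign_region_properties()].
#' @param grid A [raster_grid()]; defaults to the target image grid of the
#'   geometry's constraint tables (64 x 64 over the image extent).
#' @return A `head_phantom` object with fields `labels`, `sigma`, `eps`
#'   (matrices), `condition` (`"healthy"`), `properties`, `geometry`,
#'   `grid`, and `stroke` (`NULL`).
#' @export
build_healthy_phantom <- function(geometry, properties, grid = NULL) {
  stopifnot(inherits(geometry, "head_geometry"))
  grid <- grid %||% raster_grid(geometry$image$extent_mm,
                                geometry$image$target_px %||% 64)
  maps <- compose_maps(geometry, properties, grid)
  lv <- REGION_LEVELS
  if (!any(maps$labels == lv[["left_brain"]]) ||
      !any(maps$labels == lv[["right_brain"]]))
    stop("degenerate phantom: empty hemisphere after clipping")
  if (!any(maps$labels == lv[["csf"]]))
    stop("degenerate phantom: empty CSF region")
  structure(list(labels = maps$labels, sigma = maps$sigma, eps = maps$eps,
                 condition = "healthy", stroke = NULL,
                 properties = properties, geometry = geometry, grid = grid),
            class = "head_phantom")
}

#' @export
print.head_phantom <- function(x, ...) {
  cat("<head_phantom>", x$condition, "-", x$grid$n, "x", x$grid$n, "px\n")
  if (!is.null(x$stroke))
    cat("  lesion:", x$stroke$kind, "r =", round(x$stroke$radius, 1), "mm,",
        x$stroke$hemisphere, "hemisphere\n")
  invisible(x)
}

#' Main cerebral artery rays
#'
#' The six rays used to place stroke lesions, approximating the supply areas
#' of the main cerebral arteries. Rays start at the midpoint between the
#' Inner-ellipse centre and the topmost point of the Inner ellipse on its
#' vertical axis, and are tilted at 12, 80, 135, -12, -80, and -135 degrees
#' from the vertical axis (positive angles lean right).
#'
#' @param geometry A `head_geometry`.
#' @return A data.frame with columns `angle_deg`, `origin_x`, `origin_y`,
#'   `dir_x`, `dir_y` (unit direction), `hemisphere`.
#' @export
artery_lines <- function(geometry) {
  stopifnot(inherits(geometry, "head_geometry"))
  inner <- geometry$elements$inner
  th <- inner$tilt * pi / 180
  # midpoint of the upper half of the vertical (b) axis
  ox <- inner$center_x - sin(th) * inner$semi_b / 2
  oy <- inner$center_y + cos(th) * inner$semi_b / 2
  ang <- c(12, 80, 135, -12, -80, -135)
  data.frame(angle_deg = ang, origin_x = ox, origin_y = oy,
             dir_x = sin(ang * pi / 180), dir_y = cos(ang * pi / 180),
             hemisphere = ifelse(ang > 0, "right", "left"))
}

# Trace one artery ray through the phantom regions. Returns sampled
# parameter positions t (mm from origin) with logical membership vectors.
trace_ray <- function(geometry, ray, step = 0.5, t_max = 220) {
  reg <- geometry_regions(geometry)
  t <- seq(0, t_max, by = step)
  x <- ray$origin_x + t * ray$dir_x
  y <- ray$origin_y + t * ray$dir_y
  hemi <- if (ray$hemisphere == "left") reg$left else reg$right
  csf_e <- point_in_region(reg$csf_ellipses, x, y)
  in_hemi <- point_in_region(hemi, x, y)
  in_inner <- point_in_region(reg$inner, x, y)
  brain <- in_hemi & !csf_e
  csf <- in_inner & !brain
  list(t = t, brain = brain, csf = csf)
}

#' Insert a stroke lesion into a healthy phantom
#'
#' Places a circular lesion on one of the six [artery_lines()]. For
#' hemorrhagic stroke the circle is centred at a random point of the artery
#' inside the brain and takes the dielectric constants of blood
#' (`sigma` = 1230 mS/m, `eps_r` = 76). For ischemic stroke the circle is
#' centred on the artery just outside the brain, so the lesion is the
#' circle's intersection with the hemisphere; its conductivity is drawn
#' uniformly in 60-70% of the host hemisphere conductivity with
#' permittivity unchanged. The lesion radius is drawn between 15 mm and the
#' distance from the CSF region to the brain edge along the chosen artery;
#' the CSF region is subtracted from the lesion and the result clipped to
#' the hemisphere.
#'
#' @param phantom A healthy `head_phantom`.
#' @param kind `"hemorrhagic"` or `"ischemic"`.
#' @param seed Optional integer seed.
#' @return A new `head_phantom` with updated maps, `condition` set to
#'   `kind`, and a `stroke` descriptor (kind, artery index, centre, radius,
#'   lesion dielectrics, hemisphere).
#' @export
insert_stroke <- function(phantom, kind = c("hemorrhagic", "ischemic"),
                          seed = NULL) {
  stopifnot(inherits(phantom, "head_phantom"))
  if (phantom$condition != "healthy")
    stop("insert_stroke expects a healthy phantom")
  kind <- match.arg(kind)
  geom <- phantom$geometry
  arteries <- artery_lines(geom)
  min_radius <- 15
  with_local_seed(seed, {
    order_idx <- sample.int(nrow(arteries))
    for (ai in order_idx) {
      ray <- arteries[ai, ]
      tr <- trace_ray(geom, ray)
      bt <- tr$t[tr$brain]
      if (length(bt) < 2) next
      t_edge <- max(bt)                       # brain boundary along the ray
      csf_before <- tr$t[tr$csf & tr$t <= t_edge]
      t_csf <- if (length(csf_before) > 0) max(csf_before) else 0
      r_max <- t_edge - t_csf
      if (r_max < min_radius) next
      radius <- stats::runif(1, min_radius, r_max)
      if (kind == "hemorrhagic") {
        t_c <- sample(bt, 1)
        sigma_lesion <- STROKE_HEMORRHAGIC$sigma
        eps_lesion <- STROKE_HEMORRHAGIC$eps
      } else {
        t_c <- t_edge + stats::runif(1, 0.05, 0.85) * radius
        sigma_lesion <- stats::runif(1, ISCHEMIC_SIGMA_RANGE[1],
                                     ISCHEMIC_SIGMA_RANGE[2]) *
          phantom$properties$brain$sigma
        eps_lesion <- phantom$properties$brain$eps
      }
      stroke <- list(kind = kind, artery_index = ai,
                     center_x = ray$origin_x + t_c * ray$dir_x,
                     center_y = ray$origin_y + t_c * ray$dir_y,
                     radius = radius, sigma_lesion = sigma_lesion,
                     eps_lesion = eps_lesion, hemisphere = ray$hemisphere)
      maps <- compose_maps(geom, phantom$properties, phantom$grid, stroke)
      if (!any(maps$labels == REGION_LEVELS[["lesion"]])) next
      out <- phantom
      out$labels <- maps$labels
      out$sigma <- maps$sigma
      out$eps <- maps$eps
      out$condition <- kind
      out$stroke <- stroke
      return(out)
    }
    stop("no admissible lesion found on any artery (ray gap < ", min_radius,
         " mm)")
  })
}

#' Re-rasterize a phantom on another grid
#'
#' Property maps are defined by the phantom's geometry, region properties,
#' and stroke descriptor, so they can be regenerated at any resolution,
#' e.g. on the forward-solver grid.
#'
#' @param phantom A `head_phantom`.
#' @param grid A [raster_grid()].
#' @return A `head_phantom` on the new grid.
#' @export
phantom_on_grid <- function(phantom, grid) {
  stopifnot(inherits(phantom, "head_phantom"), inherits(grid, "raster_grid"))
  maps <- compose_maps(phantom$geometry, phantom$properties, grid,
                       phantom$stroke)
  out <- phantom
  out$labels <- maps$labels
  out$sigma <- maps$sigma
  out$eps <- maps$eps
  out$grid <- grid
  out
}

#' Export phantom maps
#'
#' Writes the conductivity and permittivity maps as CSV grids and the
#' region-label image as an indexed PNG (when the `png` package is
#' available) for visual inspection.
#'
#' @param phantom A `head_phantom`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the paths written.
#' @export
export_phantom <- function(phantom, dir, stem = "phantom") {
  stopifnot(inherits(phantom, "head_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sigma = file.path(dir, paste0(stem, "_sigma.csv")),
             eps = file.path(dir, paste0(stem, "_eps.csv")),
             labels = file.path(dir, paste0(stem, "_labels.png")))
  utils::write.table(phantom$sigma, paths["sigma"], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(phantom$eps, paths["eps"], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  if (requireNamespace("png", quietly = TRUE)) {
    pal <- c("#000000", "#d9a066", "#8f563b", "#5b6ee1", "#3f3f74",
             "#99e550", "#d95763")
    lab <- phantom$labels
    img <- array(0, dim = c(nrow(lab), ncol(lab), 3))
    for (k in seq_along(pal)) {
      rgb <- grDevices::col2rgb(pal[k]) / 255
      m <- t(lab)[nrow(lab):1, , drop = FALSE] == (k - 1L)
      for (ch in 1:3) img[, , ch][m] <- rgb[ch]
    }
    png::writePNG(img, paths["labels"])
  } else {
    paths <- paths[c("sigma", "eps")]
  }
  invisible(paths)
}
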