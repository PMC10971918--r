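# Forward problem: quasi-static complex-permittivity field of the insulated
# 16-electrode sensor belt, solved with a finite-volume discretization, and
# complex capacitance frames via Gauss-law surface integration.

EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Complex relative permittivity
#'
#' Combines relative permittivity and conductivity into the complex relative
#' permittivity `eps_r - j * sigma / (omega * eps0)` used by the forward
#' solver at a single angular frequency.
#'
#' @param eps_r Relative permittivity (>= 0), vector or matrix.
#' @param sigma_mS_m Conductivity in mS/m (>= 0), same shape.
#' @param frequency_Hz Frequency in Hz (> 0); default 64 MHz.
#' @return Complex values, same shape as the inputs.
#' @export
#' @examples
#' complex_permittivity(46.46, 378)  # brain tissue at 64 MHz
complex_permittivity <- function(eps_r, sigma_mS_m, frequency_Hz = 64e6) {
  if (any(frequency_Hz <= 0)) stop("frequency must be positive")
  if (any(sigma_mS_m < 0)) stop("conductivity must be non-negative")
  omega <- 2 * pi * frequency_Hz
  eps_r - 1i * (sigma_mS_m / 1000) / (omega * EPS0)
}

#' Insulated-electrode sensor belt
#'
#' Describes the capacitively coupled sensor: `n_electrodes` surface
#' electrodes of equal angular span on the outside of a dielectric
#' insulation layer wrapped around the fixed head outline, enclosed by a
#' grounded screen. All lengths in mm.
#'
#' @param n_electrodes Number of electrodes (default 16).
#' @param belt_semi_x,belt_semi_y Semiaxes of the belt (head outline), mm.
#' @param insulation_mm Insulation layer thickness (> 0); forms the coupling
#'   capacitance in series with the head impedance.
#' @param eps_insulation Relative permittivity of the insulation.
#' @param coverage Fraction of each electrode's angular sector covered by
#'   metal (default 0.8, centred).
#' @param electrode_mm Radial thickness of the electrode conductor shell.
#' @param screen_gap_mm Air gap between the electrode surface and the
#'   grounded screen.
#' @param voltage Excitation potential, volts.
#' @param frequency_Hz Operating frequency.
#' @return A `sensor_model` object.
#' @export
sensor_model <- function(n_electrodes = 16, belt_semi_x = 77,
                         belt_semi_y = 105, insulation_mm = 4,
                         eps_insulation = 4, coverage = 0.8,
                         electrode_mm = 6, screen_gap_mm = 20, voltage = 1,
                         frequency_Hz = 64e6) {
  stopifnot(n_electrodes >= 2, insulation_mm > 0, coverage > 0, coverage < 1,
            electrode_mm > 0, screen_gap_mm > 0, voltage != 0)
  structure(list(n_electrodes = as.integer(n_electrodes),
                 belt_semi_x = belt_semi_x, belt_semi_y = belt_semi_y,
                 insulation_mm = insulation_mm,
                 eps_insulation = eps_insulation, coverage = coverage,
                 electrode_mm = electrode_mm,
                 screen_gap_mm = screen_gap_mm, voltage = voltage,
                 frequency_Hz = frequency_Hz),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat("<sensor_model>", x$n_electrodes, "electrodes on",
      x$belt_semi_x, "x", x$belt_semi_y, "mm belt;",
      x$insulation_mm, "mm insulation (eps_r", x$eps_insulation, ");",
      x$frequency_Hz / 1e6, "MHz\n")
  invisible(x)
}

#' Default solver grid for a sensor
#'
#' A square raster that covers the sensor's grounded screen with a small
#' margin.
#'
#' @param sensor A [sensor_model()].
#' @param n Grid resolution per side (default 64, the minimum supported).
#' @return A [raster_grid()].
#' @export
solver_grid <- function(sensor, n = 64) {
  r <- max(sensor$belt_semi_x, sensor$belt_semi_y) +
    sensor$insulation_mm + sensor$screen_gap_mm
  raster_grid(2 * r + 6, n)
}

#' Complex permittivity field of a phantom
#'
#' Rasterizes a phantom's dielectric maps on a solver grid and converts them
#' to complex relative permittivity at the sensor frequency.
#'
#' @param phantom A `head_phantom`.
#' @param grid Solver [raster_grid()]; the phantom is re-rasterized on it.
#' @param frequency_Hz Frequency used for the conversion.
#' @param subsample Sub-pixel sampling factor for area-weighted material
#'   assignment at tissue boundaries (1 = plain pixel-centre sampling).
#' @return A `permittivity_field` object (complex matrix `eps`, `grid`,
#'   `frequency_Hz`).
#' @export
permittivity_field <- function(phantom, grid, frequency_Hz = 64e6,
                               subsample = 3) {
  stopifnot(inherits(phantom, "head_phantom"), subsample >= 1)
  if (subsample == 1) {
    ph <- phantom_on_grid(phantom, grid)
    eps_r <- ph$eps
    sig <- ph$sigma
  } else {
    fine <- raster_grid(grid$extent, grid$n * subsample)
    ph <- phantom_on_grid(phantom, fine)
    eps_r <- block_average(ph$eps, subsample)
    sig <- block_average(ph$sigma, subsample)
  }
  eps <- complex_permittivity(eps_r, sig, frequency_Hz)
  structure(list(eps = eps, grid = grid, frequency_Hz = frequency_Hz),
            class = "permittivity_field")
}

# Mean over k x k blocks of a (n k) x (n k) matrix.
block_average <- function(M, k) {
  n <- nrow(M) / k
  A <- colMeans(array(M, c(k, n, k * n)))       # average within row blocks
  t(colMeans(array(t(matrix(A, n, k * n)), c(k, n, n))))
}

#' Uniform permittivity field
#'
#' Homogeneous field useful for reference measurements, the empty-sensor
#' (air) case, and tests.
#'
#' @param grid Solver grid.
#' @param eps_r,sigma_mS_m Uniform material values.
#' @param head_only If `TRUE`, the material fills only the head outline
#'   (semiaxes 77 x 105 mm) with air outside; otherwise the whole domain.
#' @param frequency_Hz Frequency.
#' @param belt_semi_x,belt_semi_y Head outline semiaxes used when
#'   `head_only = TRUE`.
#' @return A `permittivity_field`.
#' @export
uniform_field <- function(grid, eps_r = 1, sigma_mS_m = 0, head_only = FALSE,
                          frequency_Hz = 64e6, belt_semi_x = 77,
                          belt_semi_y = 105) {
  val <- complex_permittivity(eps_r, sigma_mS_m, frequency_Hz)
  eps <- matrix(complex_permittivity(1, 0, frequency_Hz), grid$n, grid$n)
  if (head_only) {
    m <- rasterize(ellipse_spec(0, 0, belt_semi_x, belt_semi_y, 0), grid)
    eps[m] <- val
  } else {
    eps[] <- val
  }
  structure(list(eps = eps, grid = grid, frequency_Hz = frequency_Hz),
            class = "permittivity_field")
}

# Cell classification for the sensor on a grid. Codes: 0 interior unknown,
# -1 grounded screen (and beyond), k > 0 electrode k. Also returns the
# complex permittivity with the insulation layer stamped in; the insulation
# band is area-weighted by sub-pixel sampling so the thin layer is
# represented consistently across grid resolutions.
sensor_layout <- function(sensor, field, subsample = 3) {
  grid <- field$grid
  p <- grid_points(grid)
  ax <- sensor$belt_semi_x
  ay <- sensor$belt_semi_y
  t_ins <- sensor$insulation_mm
  t_el <- sensor$electrode_mm
  rho <- function(x, y, a, b) sqrt((x / a)^2 + (y / b)^2)
  rho_el <- rho(p$x, p$y, ax + t_ins, ay + t_ins)  # electrode inner surface
  rho_el_out <- rho(p$x, p$y, ax + t_ins + t_el, ay + t_ins + t_el)
  rho_scr <- rho(p$x, p$y, ax + t_ins + t_el + sensor$screen_gap_mm,
                 ay + t_ins + t_el + sensor$screen_gap_mm)
  code <- integer(length(p$x))
  code[rho_scr >= 1] <- -1L
  # clockwise angle from the +y axis; electrode 1 centred at the top
  phi <- atan2(p$x, p$y) * 180 / pi
  sector <- 360 / sensor$n_electrodes
  half_span <- sector * sensor$coverage / 2
  shell <- rho_el >= 1 & rho_el_out <= 1 & code == 0L
  for (k in seq_len(sensor$n_electrodes)) {
    center <- (k - 1) * sector
    d <- (phi - center + 180) %% 360 - 180
    code[shell & abs(d) <= half_span] <- k
  }
  eps <- as.vector(field$eps)
  # area-weighted insulation stamp: cells near the band blend their field
  # value with the insulation permittivity by sub-pixel coverage
  near <- which(rho(p$x, p$y, ax, ay) >= 1 - 2 * grid$h / min(ax, ay) &
                  rho_el <= 1 + 2 * grid$h / min(ax, ay))
  if (length(near) > 0) {
    off <- (seq_len(subsample) - (subsample + 1) / 2) * grid$h / subsample
    frac <- numeric(length(near))
    for (dx in off) for (dy in off) {
      sx <- p$x[near] + dx; sy <- p$y[near] + dy
      frac <- frac + (rho(sx, sy, ax, ay) >= 1 & rho(sx, sy, ax + t_ins,
                                                     ay + t_ins) <= 1)
    }
    frac <- frac / subsample^2
    eps[near] <- eps[near] * (1 - frac) + frac * sensor$eps_insulation
  }
  list(code = code, eps = eps, n = grid$n)
}

# Assemble the finite-volume system for all excitations at once.
# Returns the LU-factorized real-block operator, the per-electrode RHS,
# index maps, and face data for Gauss integration and sensitivities.
solver_system <- function(field, sensor) {
  lay <- sensor_layout(sensor, field)
  grid <- field$grid
  p <- grid_points(grid)
  ax <- sensor$belt_semi_x + sensor$insulation_mm
  ay <- sensor$belt_semi_y + sensor$insulation_mm
  bx <- ax + sensor$electrode_mm
  by <- ay + sensor$electrode_mm
  sector <- 360 / sensor$n_electrodes
  half_span <- sector * sensor$coverage / 2
  is_metal <- function(x, y) {
    r1 <- sqrt((x / ax)^2 + (y / ay)^2)
    r2 <- sqrt((x / bx)^2 + (y / by)^2)
    phi <- atan2(x, y) * 180 / pi
    d <- (phi %% sector + sector / 2) %% sector - sector / 2
    r1 >= 1 & r2 <= 1 & abs(d) <= half_span
  }
  # bisection for the metal-surface crossing along a face, in cell units
  metal_t <- function(dom_c, met_c) {
    x0 <- p$x[dom_c]; y0 <- p$y[dom_c]
    dx <- p$x[met_c] - x0; dy <- p$y[met_c] - y0
    lo <- numeric(length(dom_c)); hi <- rep(1, length(dom_c))
    for (it in 1:25) {
      mid <- (lo + hi) / 2
      m <- is_metal(x0 + mid * dx, y0 + mid * dy)
      lo[!m] <- mid[!m]
      hi[m] <- mid[m]
    }
    (lo + hi) / 2
  }
  sys <- assemble_system(lay$code, lay$eps, lay$n, sensor$voltage,
                         sensor$n_electrodes, metal_t = metal_t)
  sys$layout <- lay
  sys$sensor <- sensor
  sys$field <- field
  sys
}

# Generic finite-volume assembly from a cell classification (`code`: 0
# unknown, -1 grounded, k > 0 electrode k) and complex permittivities.
# `metal_t` optionally gives the sub-pixel distance (in units of the cell
# size, in (0, 1]) from a domain cell centre to the electrode surface along
# a face; metal-adjacent faces then get the ghost-cell conductance
# eps_domain / t instead of the harmonic mean, which removes the first-order
# staircase error of the Dirichlet boundary.
assemble_system <- function(code, eps, n, voltage, ne, metal_t = NULL) {
  idx <- matrix(seq_len(n * n), n, n)
  # faces between horizontally and vertically adjacent cells
  fa <- c(idx[-n, ], idx[, -n])
  fb <- c(idx[-1, ], idx[, -1])
  keep <- !(code[fa] == -1L & code[fb] == -1L)  # drop screen-screen faces
  fa <- fa[keep]; fb <- fb[keep]
  g <- 2 * eps[fa] * eps[fb] / (eps[fa] + eps[fb])  # harmonic mean
  if (!is.null(metal_t)) {
    mf <- which((code[fa] > 0L) != (code[fb] > 0L))
    a_metal <- code[fa[mf]] > 0L
    dom_c <- ifelse(a_metal, fb[mf], fa[mf])
    met_c <- ifelse(a_metal, fa[mf], fb[mf])
    t <- pmin(pmax(metal_t(dom_c, met_c), 0.3), 1)
    g[mf] <- eps[dom_c] / t
  }
  unknown <- which(code == 0L)
  umap <- integer(n * n)
  umap[unknown] <- seq_along(unknown)
  nu <- length(unknown)
  a_unk <- umap[fa]; b_unk <- umap[fb]
  both <- a_unk > 0 & b_unk > 0
  ia <- c(a_unk[both], b_unk[both], a_unk[a_unk > 0], b_unk[b_unk > 0])
  ja <- c(b_unk[both], a_unk[both], a_unk[a_unk > 0], b_unk[b_unk > 0])
  va <- c(-g[both], -g[both], g[a_unk > 0], g[b_unk > 0])
  build <- function(vals) Matrix::sparseMatrix(i = ia, j = ja, x = vals,
                                               dims = c(nu, nu))
  Ar <- build(Re(va)); Ai <- build(Im(va))
  M <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  lu <- Matrix::lu(M)
  # RHS per electrode: faces between an unknown cell and that electrode
  B <- matrix(0 + 0i, nu, ne)
  el_face <- (code[fa] > 0L) != (code[fb] > 0L)  # one side is an electrode
  ef_a <- fa[el_face]; ef_b <- fb[el_face]; ef_g <- g[el_face]
  el_id <- pmax(code[ef_a], code[ef_b])
  dom <- ifelse(code[ef_a] > 0L, ef_b, ef_a)   # the non-electrode side
  for (f in seq_along(ef_a)) {
    if (code[dom[f]] == 0L)
      B[umap[dom[f]], el_id[f]] <- B[umap[dom[f]], el_id[f]] +
        ef_g[f] * voltage
  }
  list(code = code, voltage = voltage, ne = ne, lu = lu, B = B,
       unknown = unknown, umap = umap,
       faces = list(a = fa, b = fb, g = g),
       el_faces = list(a = ef_a, b = ef_b, g = ef_g, id = el_id, dom = dom),
       n = n)
}

solve_excitation <- function(sys, excited) {
  nu <- length(sys$unknown)
  b <- sys$B[, excited]
  rhs <- c(Re(b), Im(b))
  sol <- as.vector(Matrix::solve(sys$lu, rhs))
  u <- sol[seq_len(nu)] + 1i * sol[nu + seq_len(nu)]
  V <- numeric(sys$n * sys$n) + 0i               # screen and idle electrodes: 0
  V[sys$unknown] <- u
  V[sys$code == excited] <- sys$voltage
  V
}

#' Solve the quasi-static field for one excitation
#'
#' Solves `div(eps grad V) = 0` on the sensor domain with Dirichlet
#' conditions: the excited electrode at the excitation potential, all other
#' electrodes and the screen grounded. Discretization is a regular
#' finite-volume grid with harmonic-mean face permittivities; the sparse
#' system is LU-factorized and the discrete residual verified.
#'
#' @param field A `permittivity_field` (grid resolution >= 64).
#' @param sensor A [sensor_model()].
#' @param excited Excited electrode index in `1..n_electrodes`.
#' @return A `field_solution`: complex potential matrix `V` (grid shape),
#'   `excited`, and the solver internals needed by [gauss_capacitance()].
#' @export
solve_field <- function(field, sensor, excited) {
  stopifnot(inherits(field, "permittivity_field"),
            inherits(sensor, "sensor_model"))
  if (field$grid$n < 64) stop("solver grid must be at least 64 x 64")
  if (excited < 1 || excited > sensor$n_electrodes)
    stop("excited electrode out of range")
  sys <- solver_system(field, sensor)
  V <- solve_excitation(sys, excited)
  check_residual(sys, V, excited)
  structure(list(V = matrix(V, sys$n, sys$n), excited = as.integer(excited),
                 sys = sys),
            class = "field_solution")
}

# Relative residual of the discrete conservation law on unknown cells.
check_residual <- function(sys, V, excited, tol = 1e-10) {
  f <- sys$faces
  flux <- f$g * (V[f$a] - V[f$b])
  div <- numeric(sys$n * sys$n) + 0i
  # accumulate flux divergence on unknown cells only
  ta <- tapply(flux, f$a, sum)
  tb <- tapply(flux, f$b, sum)
  div[as.integer(names(ta))] <- div[as.integer(names(ta))] + ta
  div[as.integer(names(tb))] <- div[as.integer(names(tb))] - tb
  r <- max(Mod(div[sys$unknown]))
  scale <- max(Mod(flux))
  if (scale > 0 && r / scale > tol)
    stop(sprintf("solver failure: residual %.3e exceeds tolerance", r / scale))
  invisible(r)
}

#' Complex capacitance by Gauss-law integration
#'
#' Integrates the normal flux of `eps * E` over the closed contour one cell
#' off the measuring electrode's surface and divides by the potential
#' difference between excited and measuring electrodes. Capacitances are per
#' unit depth (2D), in farads per metre.
#'
#' @param solution A `field_solution` from [solve_field()].
#' @param measuring Measuring electrode index (different from the excited
#'   one).
#' @return Complex capacitance (F/m).
#' @export
gauss_capacitance <- function(solution, measuring) {
  stopifnot(inherits(solution, "field_solution"))
  sys <- solution$sys
  if (measuring == solution$excited)
    stop("measuring electrode must differ from the excited one")
  if (measuring < 1 || measuring > sys$ne)
    stop("measuring electrode out of range")
  ef <- sys$el_faces
  sel <- ef$id == measuring
  if (any(sys$code[ef$dom[sel]] > 0L))
    stop("integration contour intersects another electrode")
  V <- solution$V
  # flux into the electrode from the domain side; electrode potential is 0
  q <- sum(ef$g[sel] * (V[ef$dom[sel]] - 0))
  EPS0 * q / sys$voltage
}

#' Simulate a full measurement frame
#'
#' Excites each electrode in turn and measures the complex capacitance on
#' every other electrode, yielding the ordered-pair vector of length
#' `N * (N - 1)` (240 for 16 electrodes, 992 for 32).
#'
#' @param field A `permittivity_field`.
#' @param sensor A [sensor_model()].
#' @return A `measurement_frame`: complex `values` (length `N (N-1)`),
#'   `pairs` (data.frame `excite`, `measure`), `snr_db` (`Inf` = noiseless).
#' @export
measure_frame <- function(field, sensor) {
  stopifnot(inherits(field, "permittivity_field"),
            inherits(sensor, "sensor_model"))
  sys <- solver_system(field, sensor)
  ne <- sensor$n_electrodes
  ef <- sys$el_faces
  pairs <- expand.grid(measure = seq_len(ne), excite = seq_len(ne))
  pairs <- pairs[pairs$excite != pairs$measure, c("excite", "measure")]
  pairs <- pairs[order(pairs$excite, pairs$measure), ]
  rownames(pairs) <- NULL
  vals <- complex(nrow(pairs))
  for (i in seq_len(ne)) {
    V <- solve_excitation(sys, i)
    for (j in seq_len(ne)) {
      if (j == i) next
      sel <- ef$id == j
      q <- sum(ef$g[sel] * V[ef$dom[sel]])
      vals[pairs$excite == i & pairs$measure == j] <-
        EPS0 * q / sensor$voltage
    }
  }
  structure(list(values = vals, pairs = pairs, snr_db = Inf,
                 n_electrodes = ne),
            class = "measurement_frame")
}

#' @export
print.measurement_frame <- function(x, ...) {
  cat("<measurement_frame>", length(x$values), "ordered pairs,",
      x$n_electrodes, "electrodes; SNR",
      if (is.finite(x$snr_db)) paste(x$snr_db, "dB") else "Inf", "\n")
  invisible(x)
}

#' Add measurement noise at a peak SNR
#'
#' Adds i.i.d. Gaussian noise of equal standard deviation to the real and
#' imaginary components of every capacitance. The noise level is referenced
#' to the maximum-magnitude entry of the frame (peak SNR):
#' `sd = max(|C|) / 10^(snr_db / 20)`.
#'
#' @param frame A `measurement_frame`.
#' @param snr_db Peak signal-to-noise ratio in dB; `Inf` returns the frame
#'   unchanged.
#' @param seed Optional integer seed (fixed seed gives bit-identical noise).
#' @return A `measurement_frame` with noise added and `snr_db` recorded.
#' @export
add_measurement_noise <- function(frame, snr_db, seed = NULL) {
  stopifnot(inherits(frame, "measurement_frame"))
  if (is.infinite(snr_db)) return(frame)
  sd <- max(Mod(frame$values)) / 10^(snr_db / 20)
  with_local_seed(seed, {
    m <- length(frame$values)
    frame$values <- frame$values + complex(real = stats::rnorm(m, 0, sd),
                                           imaginary = stats::rnorm(m, 0, sd))
    frame$snr_db <- snr_db
    frame
  })
}

#' Capacitance of a concentric-annulus geometry
#'
#' Solves the field between two concentric circular electrodes (inner disk
#' of radius `r_inner` excited, outer region beyond `r_outer` grounded)
#' filled with a uniform dielectric, and integrates the Gauss flux on the
#' grounded electrode. The continuum solution is the cylindrical capacitor,
#' `C = 2 pi eps0 eps_r / ln(r_outer / r_inner)` per unit depth, making this
#' a closed-form check of the finite-volume discretization.
#'
#' @param r_inner,r_outer Electrode radii in mm (`0 < r_inner < r_outer`).
#' @param eps_r Relative permittivity of the annulus material.
#' @param n Grid resolution (default 256).
#' @param voltage Excitation potential.
#' @return List with the simulated complex capacitance `C` (F/m) and the
#'   closed-form value `C_exact`.
#' @export
annulus_capacitance <- function(r_inner, r_outer, eps_r = 1, n = 256,
                                voltage = 1) {
  stopifnot(r_inner > 0, r_outer > r_inner)
  grid <- raster_grid(2 * r_outer * 1.05, n)
  p <- grid_points(grid)
  r <- sqrt(p$x^2 + p$y^2)
  code <- integer(n * n)
  code[r <= r_inner] <- 1L
  code[r >= r_outer] <- 2L
  eps <- rep(eps_r + 0i, n * n)
  sys <- assemble_system(code, eps, n, voltage, ne = 2L)
  V <- solve_excitation(sys, 1L)
  ef <- sys$el_faces
  sel <- ef$id == 2L
  q <- sum(ef$g[sel] * V[ef$dom[sel]])
  list(C = EPS0 * q / voltage,
       C_exact = 2 * pi * EPS0 * eps_r / log(r_outer / r_inner))
}

#' Export a measurement frame to CSV
#'
#' @param frame A `measurement_frame`.
#' @param path Output CSV path; columns `excite`, `measure`, `re_C`, `im_C`.
#' @return Invisibly, `path`.
#' @export
write_frame_csv <- function(frame, path) {
  stopifnot(inherits(frame, "measurement_frame"))
  df <- cbind(frame$pairs, re_C = Re(frame$values), im_C = Im(frame$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
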