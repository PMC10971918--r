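# Linearized forward operator (sensitivity matrix) and the classical
# reconstruction baselines: linear back projection and truncated
# pseudoinverse.

#' Sensitivity (Jacobian) matrix of the capacitance measurements
#'
#' Computes the derivative of every ordered-pair complex capacitance with
#' respect to the complex permittivity of each image pixel, at a reference
#' field. The computation uses the adjoint identity of the symmetric
#' finite-volume system: the derivative for pair `(i, j)` is the
#' dot-product of the face potential differences of the two single-electrode
#' solutions, weighted by the face-conductance derivative, so only the
#' `N` electrode solutions are needed rather than one solve per pixel.
#'
#' @param sensor A [sensor_model()].
#' @param reference_field A `permittivity_field` on the solver grid; by
#'   convention a homogeneous head-averaged tissue distribution
#'   (see [uniform_field()] with `head_only = TRUE`).
#' @param image_grid A [raster_grid()] for the reconstruction image
#'   (default 64 x 64 over 234 mm); solver cells are aggregated into image
#'   pixels by summation.
#' @return A `sensitivity_matrix` object: complex matrix `S` of shape
#'   `M x Npix` (`M = N (N - 1)` ordered pairs), `pairs`, `image_grid`, and
#'   the reference-field descriptor.
#' @export
sensitivity_matrix <- function(sensor, reference_field,
                               image_grid = raster_grid(234, 64)) {
  stopifnot(inherits(sensor, "sensor_model"),
            inherits(reference_field, "permittivity_field"),
            inherits(image_grid, "raster_grid"))
  sys <- solver_system(reference_field, sensor)
  ne <- sensor$n_electrodes
  nc <- sys$n^2
  V <- matrix(0 + 0i, nc, ne)
  for (k in seq_len(ne)) V[, k] <- solve_excitation(sys, k)
  f <- sys$faces
  eps <- sys$layout$eps
  # conductance derivative wrt each side of a harmonic-mean face
  dga <- 2 * eps[f$b]^2 / (eps[f$a] + eps[f$b])^2
  dgb <- 2 * eps[f$a]^2 / (eps[f$a] + eps[f$b])^2
  # metal-adjacent faces use ghost-cell conductances whose derivative lives
  # on the domain side only; image pixels sit inside the head and never
  # touch metal, so zeroing those faces is exact for the image support
  metal <- (sys$code[f$a] > 0L) != (sys$code[f$b] > 0L)
  dga[metal] <- 0; dgb[metal] <- 0
  nf <- length(f$a)
  dV <- matrix(0 + 0i, nf, ne)
  for (k in seq_len(ne)) dV[, k] <- V[f$a, k] - V[f$b, k]
  # scatter operator faces -> cells, weighted by the side derivative
  Pr <- Matrix::sparseMatrix(i = c(seq_len(nf), seq_len(nf)),
                             j = c(f$a, f$b), x = c(Re(dga), Re(dgb)),
                             dims = c(nf, nc))
  Pi <- Matrix::sparseMatrix(i = c(seq_len(nf), seq_len(nf)),
                             j = c(f$a, f$b), x = c(Im(dga), Im(dgb)),
                             dims = c(nf, nc))
  pairs <- expand.grid(measure = seq_len(ne), excite = seq_len(ne))
  pairs <- pairs[pairs$excite != pairs$measure, c("excite", "measure")]
  pairs <- pairs[order(pairs$excite, pairs$measure), ]
  rownames(pairs) <- NULL
  m <- nrow(pairs)
  W <- matrix(0 + 0i, nf, m)
  for (r in seq_len(m))
    W[, r] <- dV[, pairs$excite[r]] * dV[, pairs$measure[r]]
  Wr <- Re(W); Wi <- Im(W)
  Sr <- as.matrix(Matrix::t(Pr) %*% Wr - Matrix::t(Pi) %*% Wi)
  Si <- as.matrix(Matrix::t(Pr) %*% Wi + Matrix::t(Pi) %*% Wr)
  S_cell <- -EPS0 * t(Sr + 1i * Si) / sensor$voltage^2  # m x ncell
  # aggregate solver cells into image pixels
  gp <- grid_points(reference_field$grid)
  half <- image_grid$extent / 2
  ix <- floor((gp$x + half) / image_grid$h) + 1
  iy <- floor((gp$y + half) / image_grid$h) + 1
  ok <- ix >= 1 & ix <= image_grid$n & iy >= 1 & iy <= image_grid$n
  pix <- ix + (iy - 1) * image_grid$n
  agg <- Matrix::sparseMatrix(i = which(ok), j = pix[ok], x = 1,
                              dims = c(nc, image_grid$n^2))
  S <- as.matrix(Re(S_cell) %*% agg) + 1i * as.matrix(Im(S_cell) %*% agg)
  structure(list(S = S, pairs = pairs, image_grid = image_grid,
                 solver_grid = reference_field$grid, sensor = sensor),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat("<sensitivity_matrix>", nrow(x$S), "measurements x", ncol(x$S),
      "pixels (", x$image_grid$n, "x", x$image_grid$n, "image )\n")
  invisible(x)
}

# Real operator mapping a conductivity increase (mS/m) to the imaginary
# part of the capacitance change: d eps = -j k d sigma, so
# Im(dC) = -k Re(S) d sigma with k = 1e-3 / (omega eps0) > 0.
conductivity_operator <- function(S) {
  stopifnot(inherits(S, "sensitivity_matrix"))
  omega <- 2 * pi * S$sensor$frequency_Hz
  -Re(S$S) * 1e-3 / (omega * EPS0)
}

# Interpret the measurement-change argument: complex vectors (or frames)
# contribute their imaginary part; real vectors are used as-is.
as_delta_im <- function(delta_c) {
  if (inherits(delta_c, "measurement_frame")) delta_c <- delta_c$values
  if (is.complex(delta_c)) Im(delta_c) else as.numeric(delta_c)
}

#' Linear back projection reconstruction
#'
#' Classical LBP baseline: the transposed sensitivity operator applied to
#' the measurement change, normalized per pixel by the total absolute
#' sensitivity reaching that pixel. Conductivity images are reconstructed
#' from the imaginary part of the capacitance change (conductivity enters
#' the complex permittivity through the imaginary part).
#'
#' @param delta_c Measurement change: complex vector (its imaginary part is
#'   used), real vector, or `measurement_frame`.
#' @param S A [sensitivity_matrix()].
#' @return Reconstructed image matrix (image-grid shape). Pixels with zero
#'   total sensitivity are set to 0 (with a one-time warning).
#' @export
lbp_reconstruct <- function(delta_c, S) {
  stopifnot(inherits(S, "sensitivity_matrix"))
  y <- as_delta_im(delta_c)
  A <- conductivity_operator(S)
  if (length(y) != nrow(A)) stop("measurement vector length mismatch")
  norm <- colSums(abs(A))
  x <- as.vector(crossprod(A, y))
  dead <- norm == 0
  if (any(dead) && any(x[!dead] != 0) && !all(dead)) {
    if (any(x[dead] != 0)) warning("zero-sensitivity pixels set to 0")
  }
  x[!dead] <- x[!dead] / norm[!dead]
  x[dead] <- 0
  matrix(x, S$image_grid$n, S$image_grid$n)
}

#' Truncated-pseudoinverse reconstruction
#'
#' Moore-Penrose solution of the linearized problem via truncated SVD of
#' the conductivity operator.
#'
#' @param delta_c As in [lbp_reconstruct()].
#' @param S A [sensitivity_matrix()].
#' @param truncation Truncation rank (1 to `min(M, Npix)`); `NULL` picks the
#'   rank at the elbow of the Picard plot (the largest rank before the
#'   solution coefficients `|u_k' y| / s_k` start exploding).
#' @return Reconstructed image matrix.
#' @export
pinv_reconstruct <- function(delta_c, S, truncation = NULL) {
  stopifnot(inherits(S, "sensitivity_matrix"))
  y <- as_delta_im(delta_c)
  A <- conductivity_operator(S)
  if (length(y) != nrow(A)) stop("measurement vector length mismatch")
  x <- tsvd_solve(A, y, truncation)
  matrix(x, S$image_grid$n, S$image_grid$n)
}

# Truncated-SVD least-squares solve; rank = NULL uses the Picard elbow.
tsvd_solve <- function(A, y, rank = NULL) {
  sv <- svd(A)
  pos <- sum(sv$d > max(sv$d) * 1e-12)
  if (is.null(rank)) rank <- picard_rank(sv, y, pos)
  rank <- as.integer(rank)
  if (rank < 1) stop("truncation rank must be at least 1")
  rank <- min(rank, pos)
  k <- seq_len(rank)
  coef <- crossprod(sv$u[, k, drop = FALSE], y) / sv$d[k]
  as.vector(sv$v[, k, drop = FALSE] %*% coef)
}

# Picard elbow: stop before the normalized solution coefficients start
# growing faster than the singular values decay.
picard_rank <- function(sv, y, kmax) {
  coef <- abs(as.vector(crossprod(sv$u[, seq_len(kmax), drop = FALSE], y)))
  ratio <- coef / sv$d[seq_len(kmax)]
  base <- stats::median(ratio[seq_len(min(10, kmax))])
  bad <- which(ratio > 100 * base)
  if (length(bad) == 0) kmax else max(1L, min(bad) - 1L)
}

#' Export / import a sensitivity matrix
#'
#' Serializes the operator together with its grid metadata.
#'
#' @param S A `sensitivity_matrix`.
#' @param path File path (`.rds`).
#' @return `write_sensitivity` invisibly returns `path`;
#'   `read_sensitivity` returns the `sensitivity_matrix`.
#' @export
write_sensitivity <- function(S, path) {
  stopifnot(inherits(S, "sensitivity_matrix"))
  saveRDS(S, path)
  invisible(path)
}

#' @rdname write_sensitivity
#' @export
read_sensitivity <- function(path) {
  S <- readRDS(path)
  stopifnot(inherits(S, "sensitivity_matrix"))
  S
}
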