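# Forward solver: complex permittivity, field solutions, Gauss-law
# capacitances, measurement frames, and noise.

test_that("complex permittivity follows the single-frequency phasor form", {
  expect_identical(complex_permittivity(5, 0), 5 - 0i)
  # white-matter values against direct scalar evaluation
  eps0 <- 8.8541878128e-12
  wm <- complex_permittivity(67.8, 292, 64e6)
  expect_equal(Re(wm), 67.8)
  expect_equal(-Im(wm), 0.292 / (2 * pi * 64e6 * eps0), tolerance = 1e-12)
  # imaginary part linear in conductivity
  expect_equal(Im(complex_permittivity(10, 500)),
               2 * Im(complex_permittivity(10, 250)))
  expect_error(complex_permittivity(10, -1), "non-negative")
  expect_error(complex_permittivity(10, 5, 0), "positive")
})

test_that("frame length is N(N-1) and degenerate two-electrode frames are reciprocal", {
  fr <- fx_frame()
  expect_length(fr$values, 240)
  expect_equal(nrow(fr$pairs), 16 * 15)
  s2 <- sensor_model(n_electrodes = 2, coverage = 0.45)
  fr2 <- measure_frame(uniform_field(solver_grid(s2, 64)), s2)
  expect_length(fr2$values, 2)
  expect_equal(fr2$values[1], fr2$values[2], tolerance = 1e-9)
})

test_that("capacitances are reciprocal and obey the maximum principle", {
  fr <- fx_frame()
  M <- matrix(NA_complex_, 16, 16)
  M[cbind(fr$pairs$excite, fr$pairs$measure)] <- fr$values
  expect_lt(max(Mod(M - t(M)) / Mod(M), na.rm = TRUE), 1e-6)
  # adjacent pairs couple more strongly than opposite pairs (air sensor)
  sens <- fx_sensor()
  fra <- measure_frame(uniform_field(solver_grid(sens, 64)), sens)
  A <- matrix(NA_complex_, 16, 16)
  A[cbind(fra$pairs$excite, fra$pairs$measure)] <- fra$values
  expect_gt(Mod(A[1, 2]), Mod(A[1, 9]))
  # potential bounded by the excitation (real-permittivity field)
  sol <- solve_field(uniform_field(solver_grid(sens, 64)), sens, 3)
  expect_lte(max(Re(sol$V)), 1 + 1e-12)
  expect_gte(min(Re(sol$V)), -1e-12)
  expect_lt(max(abs(Im(sol$V))), 1e-12)
})

test_that("uniform permittivity scaling scales all capacitances exactly", {
  sens <- fx_sensor()
  f1 <- uniform_field(solver_grid(sens, 64), eps_r = 2, sigma_mS_m = 100)
  fr1 <- measure_frame(f1, sens)
  k <- 3
  f2 <- f1; f2$eps <- f1$eps * k
  sens_k <- sensor_model(eps_insulation = sens$eps_insulation * k)
  fr2 <- measure_frame(f2, sens_k)
  expect_equal(fr2$values, k * fr1$values, tolerance = 1e-12)
})

test_that("annulus geometry reproduces the cylindrical-capacitor closed form", {
  # moderate grid here; the 256^2 check runs with the acceptance criteria
  a <- annulus_capacitance(50, 110, eps_r = 2, n = 128)
  expect_lt(Mod(a$C - a$C_exact) / Mod(a$C_exact), 0.03)
})

test_that("capacitances converge across solver grids for a smooth phantom", {
  ph <- fx_phantom()
  sens <- fx_sensor()
  fa <- measure_frame(permittivity_field(ph, solver_grid(sens, 128)), sens)
  fb <- measure_frame(permittivity_field(ph, solver_grid(sens, 256)), sens)
  rel <- Mod(fa$values - fb$values) / Mod(fb$values)
  expect_lt(median(rel), 0.05)
})

test_that("measurement noise is peak-referenced, seeded, and exact at infinite SNR", {
  fr <- fx_frame()
  expect_identical(add_measurement_noise(fr, Inf), fr)
  n1 <- add_measurement_noise(fr, 30, seed = 5)
  n2 <- add_measurement_noise(fr, 30, seed = 5)
  expect_identical(n1$values, n2$values)
  expect_identical(n1$snr_db, 30)
  # Monte-Carlo estimate of the realized peak SNR within 0.5 dB
  resid <- unlist(lapply(1:500, function(i) {
    d <- add_measurement_noise(fr, 30, seed = i)$values - fr$values
    c(Re(d), Im(d))
  }))
  snr_hat <- 20 * log10(max(Mod(fr$values)) / stats::sd(resid))
  expect_lt(abs(snr_hat - 30), 0.5)
})

test_that("measurement frames export to CSV with pair annotations", {
  fr <- fx_frame()
  path <- tempfile(fileext = ".csv")
  write_frame_csv(fr, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 240)
  expect_named(df, c("excite", "measure", "re_C", "im_C"))
  expect_equal(df$re_C, Re(fr$values))
  unlink(path)
})

test_that("solver rejects invalid electrode indices and tiny grids", {
  sens <- fx_sensor()
  f <- uniform_field(solver_grid(sens, 64))
  expect_error(solve_field(f, sens, 17), "out of range")
  expect_error(solve_field(uniform_field(raster_grid(260, 32)), sens, 1),
               "at least 64")
  sol <- solve_field(f, sens, 1)
  expect_error(gauss_capacitance(sol, 1), "differ")
})
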