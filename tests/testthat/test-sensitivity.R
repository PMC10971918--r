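# Linearized operator and the classical reconstruction baselines.

test_that("sensitivity rows are reciprocal and concentrated off-centre", {
  S <- fx_sensitivity()
  expect_equal(dim(S$S), c(240, 32 * 32))
  p <- S$pairs
  for (r in c(1, 40, 111)) {
    twin <- which(p$excite == p$measure[r] & p$measure == p$excite[r])
    expect_equal(S$S[r, ], S$S[twin, ], tolerance = 1e-9)
  }
  # central pixels carry less total sensitivity than peripheral brain pixels
  g <- S$image_grid
  cs <- colSums(abs(S$S))
  rr <- sqrt(outer(g$x^2, g$y^2, "+"))
  central <- cs[rr < 30 & cs > 0]
  peripheral <- cs[rr > 55 & rr < 72 & cs > 0]
  expect_gt(mean(peripheral), mean(central))
})

test_that("sensitivity matches finite differences with first-order residuals", {
  S <- fx_sensitivity()
  sens <- fx_sensor()
  ref <- fx_reference_field()
  fr0 <- fx_ref_frame <- measure_frame(ref, sens)
  gp <- grid_points(ref$grid)
  ig <- S$image_grid
  half <- ig$extent / 2
  ix <- floor((gp$x + half) / ig$h) + 1
  iy <- floor((gp$y + half) / ig$h) + 1
  pix <- ifelse(ix >= 1 & ix <= ig$n & iy >= 1 & iy <= ig$n,
                ix + (iy - 1) * ig$n, NA)
  # interior pixels: all of their solver cells are head tissue
  head_m <- as.vector(rasterize(ellipse_spec(0, 0, 70, 98, 0), ref$grid))
  tabulate_ok <- vapply(seq_len(ig$n^2), function(p) {
    cells <- which(!is.na(pix) & pix == p)
    length(cells) > 0 && all(head_m[cells])
  }, logical(1))
  set.seed(9)
  test_pix <- sample(which(tabulate_ok), 3)
  for (p in test_pix) {
    cells <- which(!is.na(pix) & pix == p)
    errs <- vapply(c(0.4, 0.1), function(d) {
      f2 <- ref
      f2$eps[cells] <- f2$eps[cells] + d
      dc <- measure_frame(f2, sens)$values - fr0$values
      pred <- S$S[, p] * d
      sqrt(sum(Mod(dc - pred)^2)) / sqrt(sum(Mod(dc)^2))
    }, numeric(1))
    # relative residual is O(delta): shrinks ~linearly with the step
    expect_lt(errs[2], errs[1] / 2)
    expect_lt(errs[2], 0.01)
  }
})

test_that("LBP reproduces trivial cases and localizes an inclusion", {
  S <- fx_sensitivity()
  img0 <- lbp_reconstruct(rep(0, 240), S)
  expect_equal(dim(img0), c(32, 32))
  expect_true(all(img0 == 0))
  sens <- fx_sensor()
  ref <- fx_reference_field()
  fr0 <- measure_frame(ref, sens)
  incl <- ref
  mask <- rasterize(ellipse_spec(-35, 10, 18, 18, 0), ref$grid)
  incl$eps[mask] <- complex_permittivity(46.46, 900)
  fr1 <- measure_frame(incl, sens)
  img <- lbp_reconstruct(fr1$values - fr0$values, S)
  peak <- which(img == max(img), arr.ind = TRUE)
  # maximum in the correct (left) half of the domain
  expect_lt(S$image_grid$x[peak[1]], 0)
})

test_that("truncated pseudoinverse solves toy systems exactly", {
  # square invertible system: full-rank TSVD equals the exact inverse
  A <- matrix(c(2, 0, 1, 1, 3, 0, 0, 1, 4), 3, 3)
  y <- c(1, -2, 5)
  expect_equal(cceit:::tsvd_solve(A, y, 3), solve(A, y), tolerance = 1e-10)
  # overdetermined 6-measurement, 4-pixel system vs normal equations
  set.seed(4)
  A2 <- matrix(rnorm(24), 6, 4)
  y2 <- rnorm(6)
  expect_equal(cceit:::tsvd_solve(A2, y2, 4),
               as.vector(solve(crossprod(A2), crossprod(A2, y2))),
               tolerance = 1e-10)
  # residual non-increasing in truncation rank
  A3 <- matrix(rnorm(240 * 40), 240, 40)
  y3 <- rnorm(240)
  res <- vapply(1:40, function(k)
    sqrt(sum((A3 %*% cceit:::tsvd_solve(A3, y3, k) - y3)^2)), numeric(1))
  expect_true(all(diff(res) <= 1e-9))
  expect_error(cceit:::tsvd_solve(A2, y2, 0), "at least 1")
})

test_that("pinv reconstruction runs on the real operator with auto rank", {
  S <- fx_sensitivity()
  sens <- fx_sensor()
  ref <- fx_reference_field()
  fr0 <- measure_frame(ref, sens)
  incl <- ref
  mask <- rasterize(ellipse_spec(30, -20, 20, 20, 0), ref$grid)
  incl$eps[mask] <- complex_permittivity(46.46, 700)
  dc <- measure_frame(incl, sens)$values - fr0$values
  img <- pinv_reconstruct(dc, S, truncation = 120)
  expect_equal(dim(img), c(32, 32))
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_gt(S$image_grid$x[peak[1]], 0)
  truth <- as.vector(rasterize(ellipse_spec(30, -20, 20, 20, 0),
                               S$image_grid))
  expect_gt(stats::cor(as.vector(img), truth), 0.5)
  # automatic Picard rank also returns a finite image
  expect_true(all(is.finite(pinv_reconstruct(dc, S))))
})
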