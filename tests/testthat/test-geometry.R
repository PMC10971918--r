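# Geometric primitives, region algebra, rasterization, and the constrained
# geometry sampler.

test_that("ellipse perimeter matches the head-circumference value and closed forms", {
  expect_equal(round(ellipse_perimeter(105, 77)), 575)
  expect_equal(ellipse_perimeter(105, 77), ellipse_perimeter(77, 105))
  for (r in c(1, 10, 77)) {
    expect_equal(ellipse_perimeter(r, r), 2 * pi * r, tolerance = 1e-9)
  }
  # independent quadrature oracle for the arclength integral
  quad <- function(a, b) {
    4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                         0, pi / 2, rel.tol = 1e-10)$value
  }
  for (ab in list(c(10, 5), c(105, 77), c(3, 40))) {
    expect_equal(ellipse_perimeter(ab[1], ab[2]), quad(ab[1], ab[2]),
                 tolerance = 1e-6)
  }
  # monotone in each semiaxis
  expect_gt(ellipse_perimeter(11, 5), ellipse_perimeter(10, 5))
  expect_gt(ellipse_perimeter(10, 6), ellipse_perimeter(10, 5))
  expect_error(ellipse_perimeter(-1, 5), "positive")
  expect_error(ellipse_spec(0, 0, 0, 5), "positive")
})

test_that("point membership honours boolean region semantics", {
  e1 <- ellipse_spec(0, 0, 10, 5, 30)
  e2 <- ellipse_spec(6, 0, 8, 8, 0)
  expect_true(point_in_region(e1, 0, 0))
  expect_false(point_in_region(e1, 100, 100))
  # boundary counts as inside (untilted ellipse endpoint)
  e3 <- ellipse_spec(0, 0, 10, 5, 0)
  expect_true(point_in_region(e3, 10, 0))
  xs <- runif(500, -15, 20); ys <- runif(500, -15, 15)
  a <- point_in_region(e1, xs, ys); b <- point_in_region(e2, xs, ys)
  expect_identical(point_in_region(region_union(e1, e2), xs, ys), a | b)
  expect_identical(point_in_region(region_intersect(e1, e2), xs, ys), a & b)
  expect_identical(point_in_region(region_diff(e1, e2), xs, ys), a & !b)
  # self-difference is empty everywhere
  expect_false(any(point_in_region(region_diff(e1, e1), xs, ys)))
  # half planes: the two sides partition the plane (shared boundary aside)
  hl <- half_plane_spec(2, 0, 10, "left")
  hr <- half_plane_spec(2, 0, 10, "right")
  l <- point_in_region(hl, xs, ys); r <- point_in_region(hr, xs, ys)
  expect_true(all(l | r))
  expect_true(point_in_region(hl, -50, 0))
  expect_true(point_in_region(hr, 50, 0))
})

test_that("rasterization converges to analytic areas and respects partitions", {
  g <- raster_grid(50, 16)
  expect_true(all(rasterize(ellipse_spec(0, 0, 100, 100, 0), g)))
  # circle of radius 20 mm on a 512^2 grid of 220 mm extent: area within 1%
  g2 <- raster_grid(220, 512)
  m <- rasterize(ellipse_spec(0, 0, 20, 20, 0), g2)
  area <- sum(m) * g2$h^2
  expect_lt(abs(area - pi * 400) / (pi * 400), 0.01)
  # half-plane split partitions a mask exactly
  e <- ellipse_spec(3, -2, 30, 18, 25)
  g3 <- raster_grid(100, 64)
  hl <- half_plane_spec(1, 0, -15, "left")
  hr <- half_plane_spec(1, 0, -15, "right")
  whole <- rasterize(e, g3)
  left <- rasterize(region_intersect(e, hl), g3)
  right <- rasterize(region_intersect(e, hr), g3)
  expect_identical(whole, left | right)
})

test_that("degenerate sampler (all half-ranges zero) returns the mean geometry", {
  tab0 <- fx_tables_degenerate()
  g <- sample_geometry(tab0, seed = 1)
  gm <- mean_geometry(tab0)
  expect_equal(g$elements, gm$elements)
  expect_equal(g$midline, gm$midline)
})

test_that("sampled parameters stay in range, are reproducible, and centre on the table means", {
  tab <- fx_tables()
  g1 <- sample_geometry(tab, seed = 42)
  g2 <- sample_geometry(tab, seed = 42)
  expect_identical(g1$params, g2$params)
  n <- 200
  draws <- lapply(seq_len(n), function(i) sample_geometry(tab, seed = i))
  # every raw parameter within its mean +/- half-range window
  for (el in c("inner", "ldown", "rup", "center_csf")) {
    spec <- tab$elements[[el]]
    for (f in c("center_x", "center_y", "size_x", "size_y", "tilt")) {
      v <- vapply(draws, function(d) d$params[[el]][[f]], numeric(1))
      expect_true(all(v >= spec[[f]]$mean - spec[[f]]$hr &
                        v <= spec[[f]]$mean + spec[[f]]$hr),
                  label = paste(el, f, "in range"))
    }
  }
  # Monte-Carlo check: means of weakly-rejected parameters near table means
  # (truncated normal, sd = hr/2, so SE = hr / (2 sqrt(n)) at most)
  for (el in c("inner", "lup")) {
    spec <- tab$elements[[el]]
    for (f in c("center_x", "center_y", "tilt")) {
      v <- vapply(draws, function(d) d$params[[el]][[f]], numeric(1))
      se <- spec[[f]]$hr / (2 * sqrt(n))
      expect_lt(abs(mean(v) - spec[[f]]$mean), 4 * se + 1e-12)
    }
  }
  # accepted samples satisfy the printed area-fraction windows
  fr <- vapply(draws[1:25], function(d) unlist(area_fractions(d)), numeric(5))
  expect_true(all(fr["brain_pct", ] >= 17 & fr["brain_pct", ] <= 29))
  expect_true(all(fr["csf_pct", ] >= 17 & fr["csf_pct", ] <= 29))
  expect_true(all(fr["rest_pct", ] >= 8 & fr["rest_pct", ] <= 19))
  expect_true(all(fr["hemi_ratio_pct", ] >= 91 & fr["hemi_ratio_pct", ] <= 106))
})

test_that("perturbation approach adds calibrated noise and preserves validity", {
  tab <- fx_tables()
  base <- sample_geometry(tab, seed = 7)
  expect_identical(perturb_geometry(base, tab, relative_sd = 0), base)
  p1 <- perturb_geometry(base, tab, 0.05, seed = 3)
  # every free parameter moves (continuous noise)
  for (el in names(p1$params)) {
    expect_true(all(p1$params[[el]] != base$params[[el]]),
                label = paste("all", el, "params perturbed"))
  }
  # pooled empirical sd of (perturbed - base) / hr matches relative_sd
  hrs <- function(el, fs) vapply(fs, function(f) {
    spec <- if (el == "midline") tab$midline[[f]]
    else if (el %in% names(tab$elements)) tab$elements[[el]][[f]]
    else tab$satellites[[el]][[f]]
    spec$hr
  }, numeric(1))
  z <- unlist(lapply(1:150, function(i) {
    p <- perturb_geometry(base, tab, 0.05, seed = 1000 + i)
    unlist(lapply(names(p$params), function(el) {
      fs <- names(p$params[[el]])
      (p$params[[el]] - base$params[[el]]) / hrs(el, fs)
    }))
  }))
  expect_lt(abs(stats::sd(z) - 0.05) / 0.05, 0.10)
  # perturbed geometry still satisfies the acceptance windows
  fr <- area_fractions(p1)
  expect_true(fr$brain_pct >= 17 && fr$brain_pct <= 29)
  expect_true(fr$rest_pct >= 8 && fr$rest_pct <= 19)
})
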