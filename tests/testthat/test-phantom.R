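# Phantom assembly: dielectric assignment, region maps, artery rays, and
# stroke insertion.

test_that("region properties honour the priors and the physiological ordering", {
  pri0 <- region_priors()
  pri0$eps_sd <- 0; pri0$sigma_sd <- 0
  p <- assign_region_properties(pri0, seed = 1)
  expect_equal(p$brain$sigma, 378)
  expect_equal(p$csf$sigma, 788)
  expect_equal(p$skull$eps, 14.79)
  draws <- lapply(1:1000, function(i) assign_region_properties(seed = i))
  bs <- vapply(draws, function(d) d$brain$sigma, numeric(1))
  # sample mean within 3 standard errors of the prior mean
  expect_lt(abs(mean(bs) - 378), 3 * 59 / sqrt(1000))
  ok <- vapply(draws, function(d)
    d$csf$sigma > d$brain$sigma && d$brain$sigma > d$skull$sigma &&
      d$csf$eps > d$brain$eps && d$brain$eps > d$skull$eps, logical(1))
  expect_true(all(ok))
})

test_that("healthy phantom maps partition the grid with sane labels", {
  ph <- fx_phantom()
  expect_s3_class(ph, "head_phantom")
  expect_identical(ph$condition, "healthy")
  expect_null(ph$stroke)
  expect_true(all(ph$labels %in% 0:5))
  # the grid centre carries brain or CSF, never skull or skin
  n <- ph$grid$n
  centre <- ph$labels[n / 2, n / 2]
  expect_true(centre %in% 3:5)
  # free space outside the head
  expect_equal(ph$sigma[1, 1], 0)
  expect_equal(ph$eps[1, 1], 1)
  # property maps piecewise constant on labels
  for (lv in 1:5) {
    if (any(ph$labels == lv)) {
      expect_length(unique(ph$sigma[ph$labels == lv]), 1)
      expect_length(unique(ph$eps[ph$labels == lv]), 1)
    }
  }
})

test_that("artery rays have the published angles and reach the brain", {
  ph <- fx_phantom()
  ar <- artery_lines(ph$geometry)
  expect_setequal(ar$angle_deg, c(12, 80, 135, -12, -80, -135))
  # mirror pairs share the anchor and reflect about the vertical
  for (a in c(12, 80, 135)) {
    i <- which(ar$angle_deg == a); j <- which(ar$angle_deg == -a)
    expect_equal(ar$dir_x[i], -ar$dir_x[j])
    expect_equal(ar$dir_y[i], ar$dir_y[j])
  }
  expect_length(unique(ar$origin_x), 1)
  # lateral and posterior rays always cross brain tissue; the near-vertical
  # +/-12 degree rays may run up the interhemispheric CSF fissure, so at
  # least four of six rays hit in every sampled phantom
  tab <- fx_tables()
  for (s in 1:10) {
    g <- sample_geometry(tab, seed = 300 + s)
    rays <- artery_lines(g)
    hit <- vapply(seq_len(6), function(k)
      any(cceit:::trace_ray(g, rays[k, ])$brain), logical(1))
    expect_true(all(hit[abs(rays$angle_deg) > 15]),
                label = paste("seed", 300 + s, "lateral rays hit brain"))
    expect_gte(sum(hit), 4)
  }
})

test_that("stroke insertion carries the lesion dielectrics and set algebra", {
  ph <- fx_phantom()
  hem <- insert_stroke(ph, "hemorrhagic", seed = 21)
  isc <- insert_stroke(ph, "ischemic", seed = 22)
  expect_identical(insert_stroke(ph, "hemorrhagic", seed = 21), hem)
  # blood dielectrics for hemorrhagic lesions
  expect_true(all(hem$sigma[hem$labels == 6] == 1230))
  expect_true(all(hem$eps[hem$labels == 6] == 76))
  # ischemic conductivity fraction of the host brain tissue
  ratio <- unique(isc$sigma[isc$labels == 6]) / ph$properties$brain$sigma
  expect_length(ratio, 1)
  expect_gte(ratio, 0.60)
  expect_lte(ratio, 0.70)
  expect_equal(unique(isc$eps[isc$labels == 6]), ph$properties$brain$eps)
  for (st in list(hem, isc)) {
    expect_gte(st$stroke$radius, 15)
    # lesion replaced brain pixels of its own hemisphere only
    hemi_lab <- if (st$stroke$hemisphere == "left") 3 else 4
    expect_true(all(ph$labels[st$labels == 6] == hemi_lab))
    # maps restored exactly outside the lesion
    expect_true(all((st$sigma == ph$sigma)[st$labels != 6]))
    expect_true(all((st$labels == ph$labels)[st$labels != 6]))
  }
  # conductivity shifts in the brain region: blood raises, ischemia lowers
  brain_px <- function(p) p$sigma[p$labels %in% c(3, 4, 6)]
  expect_gt(mean(brain_px(hem)), mean(brain_px(ph)))
  expect_lt(mean(brain_px(isc)), mean(brain_px(ph)))
  expect_error(insert_stroke(hem, "ischemic"), "healthy")
})

test_that("phantom maps export to CSV grids", {
  ph <- fx_phantom()
  dir <- tempfile("phx")
  paths <- export_phantom(ph, dir)
  expect_true(file.exists(paths[["sigma"]]))
  sig <- as.matrix(utils::read.csv(paths[["sigma"]], header = FALSE))
  expect_equal(dim(sig), dim(ph$sigma))
  expect_equal(unname(sig), unname(ph$sigma), tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("phantoms re-rasterize consistently on other grids", {
  ph <- fx_phantom()
  hem <- insert_stroke(ph, "hemorrhagic", seed = 21)
  p2 <- phantom_on_grid(hem, raster_grid(234, 128))
  expect_equal(dim(p2$sigma), c(128, 128))
  # area of each region roughly preserved across resolutions
  for (lv in c(3, 4, 5, 6)) {
    a64 <- mean(hem$labels == lv)
    a128 <- mean(p2$labels == lv)
    expect_lt(abs(a64 - a128), 0.01)
  }
})
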