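# Network primitives, backpropagation correctness, and the adversarial
# reconstructor's structural contracts.

test_that("activation, linear, and batch-norm layers follow their equations", {
  expect_equal(leaky_relu(5, 0.37), 5)
  expect_equal(leaky_relu(-2, 0.1), -0.2)
  x <- rnorm(20)
  expect_equal(leaky_relu(x, 1), x)
  # linear layer: identity weights, zero input, random case vs hand product
  W <- diag(4)
  expect_equal(as.vector(linear_layer(rnorm(4) -> v, W, rep(0, 4))), v)
  W2 <- matrix(rnorm(6), 2, 3); b2 <- rnorm(2)
  expect_equal(as.vector(linear_layer(rep(0, 3), W2, b2)), b2)
  x3 <- matrix(rnorm(9), 3, 3)
  W3 <- matrix(rnorm(6), 2, 3); b3 <- rnorm(2)
  expect_equal(linear_layer(x3, W3, b3),
               x3 %*% t(W3) + matrix(b3, 3, 2, byrow = TRUE))
  expect_error(linear_layer(rnorm(4), W3, b3), "mismatch")
  # batch norm at the running mean gives the shift only
  rs <- list(mean = c(1, 2), var = c(4, 9))
  expect_equal(as.vector(batch_norm(c(1, 2), c(3, 3), c(0, 0), rs)), c(0, 0))
  e <- 1e-5
  expect_equal(as.vector(batch_norm(c(2, 5), c(1, 1), c(0, 0), rs, eps = e)),
               c(1 / sqrt(4 + e), 3 / sqrt(9 + e)))
  # batch-statistics path equals a two-pass mean/variance oracle
  xb <- matrix(rnorm(50), 10, 5)
  p <- cceit:::init_bn(5)
  out <- cceit:::fwd_bn_train(xb, p, eps = 1e-5)
  mu <- colMeans(xb)
  v <- colMeans(sweep(xb, 2, mu)^2)
  oracle <- sweep(sweep(xb, 2, mu), 2, sqrt(v + 1e-5), "/")
  expect_equal(out$xhat, oracle, tolerance = 1e-12)
})

test_that("hand-derived gradients match numerical differentiation", {
  cfg <- train_config(hidden_g = c(7, 6), hidden_d = c(5, 4))
  set.seed(2)
  G <- list(l1 = cceit:::init_linear(9, 7), bn1 = cceit:::init_bn(7),
            l2 = cceit:::init_linear(7, 6), bn2 = cceit:::init_bn(6),
            l3 = cceit:::init_linear(6, 11, gain = 1))
  x <- matrix(rnorm(5 * 9), 5)
  yt <- matrix(runif(5 * 11), 5)
  lossfn <- function(G) mean(abs(cceit:::gen_forward(G, x, cfg,
                                                     train = TRUE)$y - yt))
  gf <- cceit:::gen_forward(G, x, cfg, train = TRUE)
  gr <- cceit:::gen_backward(G, gf$cache, sign(gf$y - yt) / length(yt), cfg)
  for (ly in names(gr)) for (pn in names(gr[[ly]])) {
    for (i in sample(length(G[[ly]][[pn]]), 2)) {
      e <- 1e-6
      Gp <- G; Gp[[ly]][[pn]][i] <- Gp[[ly]][[pn]][i] + e
      Gm <- G; Gm[[ly]][[pn]][i] <- Gm[[ly]][[pn]][i] - e
      num <- (lossfn(Gp) - lossfn(Gm)) / (2 * e)
      expect_equal(gr[[ly]][[pn]][i], num, tolerance = 1e-4,
                   label = paste("grad", ly, pn))
    }
  }
  # discriminator parameter and input gradients
  D <- list(l1 = cceit:::init_linear(11 + 9, 5),
            l2 = cceit:::init_linear(5, 4),
            l3 = cceit:::init_linear(4, 1, gain = 1))
  img <- matrix(runif(5 * 11), 5)
  dloss <- function(D, img) cceit:::bce_loss(
    cceit:::disc_forward(D, img, x, cfg)$p, 1)
  f <- cceit:::disc_forward(D, img, x, cfg)
  bk <- cceit:::disc_backward(D, f$cache, (f$p - 1) / 5, cfg)
  for (ly in names(D)) for (pn in c("W", "b")) {
    for (i in sample(length(D[[ly]][[pn]]), min(2, length(D[[ly]][[pn]])))) {
      e <- 1e-6
      Dp <- D; Dp[[ly]][[pn]][i] <- Dp[[ly]][[pn]][i] + e
      Dm <- D; Dm[[ly]][[pn]][i] <- Dm[[ly]][[pn]][i] - e
      num <- (dloss(Dp, img) - dloss(Dm, img)) / (2 * e)
      expect_equal(bk$grads[[ly]][[pn]][i], num, tolerance = 1e-4)
    }
  }
  for (i in sample(length(img), 3)) {
    e <- 1e-6
    ip <- img; ip[i] <- ip[i] + e
    im <- img; im[i] <- im[i] - e
    num <- (dloss(D, ip) - dloss(D, im)) / (2 * e)
    expect_equal(bk$dimage[i], num, tolerance = 1e-4)
  }
})

test_that("generator and discriminator obey their output contracts", {
  mdl <- init_cgan(480, train_config(hidden_g = c(64, 64),
                                     hidden_d = c(32, 16)), seed = 5)
  x <- rnorm(480)
  y <- generator_forward(mdl, x)
  expect_equal(dim(y), c(64, 64))
  expect_true(all(y > 0 & y < 1))
  expect_identical(generator_forward(mdl, x), y)      # deterministic
  # 2 x 240 input form accepted
  y2 <- generator_forward(mdl, rbind(x[1:240], x[241:480]))
  expect_equal(y2, y)
  expect_error(generator_forward(mdl, rnorm(100)), "input length")
  expect_error(generator_forward(mdl, rep(NA_real_, 480)), "non-finite")
  p <- discriminator_forward(mdl, y, x)
  expect_gte(p, 0); expect_lte(p, 1)
  # batch form
  X <- matrix(rnorm(3 * 480), 3)
  Y <- generator_forward(mdl, X)
  expect_equal(dim(Y), c(3, 4096))
  expect_length(discriminator_forward(mdl, Y, X), 3)
})

test_that("only the entry layers depend on the measurement-vector length", {
  cfg <- train_config()
  m16 <- init_cgan(480, cfg, seed = 1)
  m32 <- init_cgan(992 * 2, cfg, seed = 1)
  expect_equal(dim(m16$G$l1$W)[1], dim(m32$G$l1$W)[1])
  expect_false(dim(m16$G$l1$W)[2] == dim(m32$G$l1$W)[2])
  for (ly in c("l2", "l3")) {
    expect_equal(dim(m16$G[[ly]]$W), dim(m32$G[[ly]]$W))
    expect_equal(dim(m16$D[[ly]]$W), dim(m32$D[[ly]]$W))
  }
  expect_equal(dim(m32$D$l1$W)[2] - dim(m16$D$l1$W)[2], 992 * 2 - 480)
})

test_that("mean relative error implements the L2 ratio", {
  y <- rnorm(50)
  expect_equal(mean_relative_error(y, y), 0)
  expect_equal(mean_relative_error(2 * y, y), 1)
  e1 <- c(1, rep(0, 49))
  expect_equal(mean_relative_error(y + e1 * sqrt(sum(y^2)), y), 1)
  expect_error(mean_relative_error(y, rep(0, 50)), "zero norm")
})

test_that("the generator can overfit a two-sample set", {
  set.seed(12)
  n_in <- 480
  X <- matrix(rnorm(3 * n_in), 3)
  targ <- matrix(runif(3 * 4096, 0.1, 0.9), 3)
  ds <- structure(list(
    inputs = X, inputs_raw = X, targets = targ,
    labels = rep("healthy", 3), approach = rep("constraint", 3),
    split = c("train", "train", "test"),
    std = list(mean = rep(0, n_in), sd = rep(1, n_in)),
    manifest = list(frame_length = n_in / 2)), class = "cceit_dataset")
  cfg <- train_config(epochs = 400, batch_size = 2, lambda_l1 = 100,
                      hidden_g = c(128, 128), hidden_d = c(32, 16),
                      seed = 3)
  mdl <- train_cgan(ds, cfg)
  yh <- generator_forward(mdl, X[1:2, , drop = FALSE])
  expect_lt(mean(abs(yh - targ[1:2, ])), 0.05)
  expect_equal(nrow(mdl$log), 400)
})
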