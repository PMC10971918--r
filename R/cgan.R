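# Conditional adversarial reconstruction network: dense generator mapping a
# standardized 2 x 240 measurement frame to a 64 x 64 conductivity image, a
# conditioned discriminator, and the Pix2Pix-style training loop
# (adversarial BCE + L1 reconstruction term, separate learning rates).

#' Training configuration for the adversarial reconstructor
#'
#' @param lr_g,lr_d Starting learning rates of generator and discriminator
#'   (defaults 1e-3 and 1e-8, the pair found stable for the 16-electrode
#'   configuration).
#' @param epochs Training epochs (default 100).
#' @param batch_size Minibatch size.
#' @param lambda_l1 Weight of the L1 reconstruction term (Pix2Pix
#'   convention).
#' @param noise_snr_db Peak SNR of measurement-noise augmentation; `Inf`
#'   trains on the dataset inputs as stored. When finite, noise is re-drawn
#'   from the clean frames each epoch.
#' @param alpha Leaky-ReLU negative slope.
#' @param bn_eps Batch-normalization stability constant.
#' @param hidden_g Generator hidden-layer widths.
#' @param hidden_d Discriminator hidden-layer widths.
#' @param seed Training seed (shuffling, initialization, noise).
#' @param checkpoint_dir Optional directory for per-epoch checkpoints.
#' @return A `train_config` list.
#' @export
train_config <- function(lr_g = 1e-3, lr_d = 1e-8, epochs = 100,
                         batch_size = 64, lambda_l1 = 100,
                         noise_snr_db = Inf, alpha = 0.2, bn_eps = 1e-5,
                         hidden_g = c(768, 768), hidden_d = c(256, 64),
                         seed = 1, checkpoint_dir = NULL) {
  stopifnot(lr_g > 0, lr_d > 0, epochs >= 1, batch_size >= 1, lambda_l1 >= 0)
  structure(list(lr_g = lr_g, lr_d = lr_d, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lambda_l1 = lambda_l1,
                 noise_snr_db = noise_snr_db, alpha = alpha, bn_eps = bn_eps,
                 hidden_g = hidden_g, hidden_d = hidden_d, seed = seed,
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Initialize an untrained reconstruction model
#'
#' Builds generator and discriminator weights for a given measurement-vector
#' length. Only the entry linear layer of each network depends on the input
#' length; all downstream layer sizes are fixed by the 64 x 64 output.
#'
#' @param input_len Flattened measurement input length (480 for 16
#'   electrodes: real and imaginary parts of 240 pairs).
#' @param config A [train_config()].
#' @param seed Initialization seed.
#' @return A `cgan_model` with untrained weights.
#' @export
init_cgan <- function(input_len = 480, config = train_config(), seed = 1) {
  out_px <- 64L
  n_out <- out_px^2
  hg <- config$hidden_g
  hd <- config$hidden_d
  with_local_seed(seed, {
    G <- list(l1 = init_linear(input_len, hg[1]), bn1 = init_bn(hg[1]),
              l2 = init_linear(hg[1], hg[2]), bn2 = init_bn(hg[2]),
              l3 = init_linear(hg[2], n_out, gain = 1))
    D <- list(l1 = init_linear(n_out + input_len, hd[1]),
              l2 = init_linear(hd[1], hd[2]),
              l3 = init_linear(hd[2], 1, gain = 1))
    structure(list(G = G, D = D, config = config, input_len = input_len,
                   out_px = out_px, log = NULL),
              class = "cgan_model")
  })
}

#' @export
print.cgan_model <- function(x, ...) {
  np <- function(net) sum(vapply(net, function(l)
    sum(vapply(l[names(l) %in% c("W", "b", "g")], length, numeric(1))),
    numeric(1)))
  cat("<cgan_model> input", x$input_len, "-> output", x$out_px, "x",
      x$out_px, "; G", np(x$G), "params, D", np(x$D), "params")
  if (!is.null(x$log)) cat(";", nrow(x$log), "epochs trained")
  cat("\n")
  invisible(x)
}

# generator forward pass; train mode uses batch statistics and returns the
# caches needed for backpropagation (and updated running stats)
gen_forward <- function(G, x, config, train = FALSE) {
  a1 <- fwd_linear(x, G$l1)
  if (train) {
    b1 <- fwd_bn_train(a1$y, G$bn1, config$bn_eps)
    G$bn1 <- b1$p
  } else {
    b1 <- list(y = batch_norm(a1$y, G$bn1$g, G$bn1$b,
                              list(mean = G$bn1$run_mean,
                                   var = G$bn1$run_var), config$bn_eps))
  }
  r1 <- fwd_lrelu(b1$y, config$alpha)
  a2 <- fwd_linear(r1$y, G$l2)
  if (train) {
    b2 <- fwd_bn_train(a2$y, G$bn2, config$bn_eps)
    G$bn2 <- b2$p
  } else {
    b2 <- list(y = batch_norm(a2$y, G$bn2$g, G$bn2$b,
                              list(mean = G$bn2$run_mean,
                                   var = G$bn2$run_var), config$bn_eps))
  }
  r2 <- fwd_lrelu(b2$y, config$alpha)
  a3 <- fwd_linear(r2$y, G$l3)
  y <- sigmoid(a3$y)
  list(y = y, G = G,
       cache = if (train) list(a1 = a1, b1 = b1, r1 = r1, a2 = a2, b2 = b2,
                               r2 = r2, a3 = a3, y = y))
}

# gradient of the generator parameters given dL/dy (post-sigmoid)
gen_backward <- function(G, cache, dy, config) {
  da3 <- dy * cache$y * (1 - cache$y)
  g3 <- bwd_linear(da3, cache$a3, G$l3)
  dr2 <- bwd_lrelu(g3$dx, cache$r2, config$alpha)
  g_bn2 <- bwd_bn(dr2, cache$b2, G$bn2)
  g2 <- bwd_linear(g_bn2$dx, cache$a2, G$l2)
  dr1 <- bwd_lrelu(g2$dx, cache$r1, config$alpha)
  g_bn1 <- bwd_bn(dr1, cache$b1, G$bn1)
  g1 <- bwd_linear(g_bn1$dx, cache$a1, G$l1)
  list(l1 = list(W = g1$dW, b = g1$db),
       bn1 = list(g = g_bn1$dg, b = g_bn1$db),
       l2 = list(W = g2$dW, b = g2$db),
       bn2 = list(g = g_bn2$dg, b = g_bn2$db),
       l3 = list(W = g3$dW, b = g3$db))
}

disc_forward <- function(D, image, cond, config) {
  x <- cbind(image, cond)
  a1 <- fwd_linear(x, D$l1)
  r1 <- fwd_lrelu(a1$y, config$alpha)
  a2 <- fwd_linear(r1$y, D$l2)
  r2 <- fwd_lrelu(a2$y, config$alpha)
  a3 <- fwd_linear(r2$y, D$l3)
  p <- sigmoid(a3$y)
  list(p = p, cache = list(a1 = a1, r1 = r1, a2 = a2, r2 = r2, a3 = a3,
                           p = p, n_img = ncol(image)))
}

# backprop through the discriminator; returns parameter gradients and the
# gradient with respect to the image input (for the generator update)
disc_backward <- function(D, cache, da3, config) {
  g3 <- bwd_linear(da3, cache$a3, D$l3)
  dr2 <- bwd_lrelu(g3$dx, cache$r2, config$alpha)
  g2 <- bwd_linear(dr2, cache$a2, D$l2)
  dr1 <- bwd_lrelu(g2$dx, cache$r1, config$alpha)
  g1 <- bwd_linear(dr1, cache$a1, D$l1)
  list(grads = list(l1 = list(W = g1$dW, b = g1$db),
                    l2 = list(W = g2$dW, b = g2$db),
                    l3 = list(W = g3$dW, b = g3$db)),
       dimage = g1$dx[, seq_len(cache$n_img), drop = FALSE])
}

bce_loss <- function(p, target) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Generator inference
#'
#' Maps measurement inputs through the trained generator (inference mode:
#' batch normalization uses the running statistics; no stochastic layers,
#' so identical inputs give identical outputs).
#'
#' @param model A `cgan_model`.
#' @param measurements A single measurement input (length `input_len`
#'   vector or `2 x M` matrix) or a batch (n x `input_len` matrix), already
#'   standardized as in the training dataset.
#' @return A 64 x 64 image matrix for a single input, otherwise an
#'   `n x 4096` matrix of flattened images. Values lie in (0, 1).
#' @export
generator_forward <- function(model, measurements) {
  stopifnot(inherits(model, "cgan_model"))
  single <- FALSE
  if (is.matrix(measurements) && nrow(measurements) == 2 &&
      2 * ncol(measurements) == model$input_len) {
    measurements <- c(t(measurements)[, 1], t(measurements)[, 2])
  }
  if (is.null(dim(measurements))) {
    if (length(measurements) != model$input_len)
      stop("input length ", length(measurements), " != ", model$input_len)
    measurements <- matrix(measurements, 1)
    single <- TRUE
  }
  if (any(!is.finite(measurements))) stop("non-finite measurement input")
  y <- gen_forward(model$G, measurements, model$config, train = FALSE)$y
  if (single) matrix(y[1, ], model$out_px, model$out_px) else y
}

#' Discriminator inference
#'
#' Probability that an image is a ground-truth image given its conditioning
#' measurement vector. After successful adversarial training this tends to
#' 0.5 on both real and reconstructed images.
#'
#' @param model A `cgan_model`.
#' @param image A 64 x 64 matrix (or n x 4096 batch).
#' @param conditioning Measurement input (length `input_len`, or n x
#'   `input_len`).
#' @return Probability in `[0, 1]` (vector for batches).
#' @export
discriminator_forward <- function(model, image, conditioning) {
  stopifnot(inherits(model, "cgan_model"))
  if (is.matrix(image) && nrow(image) == model$out_px &&
      ncol(image) == model$out_px) image <- matrix(as.vector(image), 1)
  if (is.null(dim(conditioning))) conditioning <- matrix(conditioning, 1)
  p <- disc_forward(model$D, image, conditioning, model$config)$p
  as.vector(p)
}

#' Mean relative error between reconstruction and reference
#'
#' `IE = ||yhat - y||_2 / ||y||_2`, the per-sample training-quality index
#' tracked on the test split during training.
#'
#' @param yhat,y Numeric vectors/matrices of equal length.
#' @return Non-negative scalar.
#' @export
#' @examples
#' mean_relative_error(c(2, 0), c(1, 0))  # 1
mean_relative_error <- function(yhat, y) {
  ny <- sqrt(sum(y^2))
  if (ny == 0) stop("reference has zero norm")
  sqrt(sum((yhat - y)^2)) / ny
}

# mean per-sample IE over rows
batch_ie <- function(yhat, y) {
  mean(vapply(seq_len(nrow(y)), function(i)
    mean_relative_error(yhat[i, ], y[i, ]), numeric(1)))
}

#' Train the conditional adversarial reconstructor
#'
#' Alternating Pix2Pix-style updates: the discriminator minimizes BCE with
#' labels 1 for ground-truth and 0 for reconstructed images (conditioned on
#' the measurement vector); the generator minimizes the adversarial BCE
#' (towards label 1) plus `lambda_l1` times the L1 reconstruction error.
#' Both use Adam (beta1 = 0.5) with separate learning rates. The mean
#' relative error on the test split is logged each epoch. Optional
#' measurement-noise augmentation re-draws noise from the clean frames each
#' epoch at the configured peak SNR.
#'
#' @param dataset A `cceit_dataset` with train/test split.
#' @param config A [train_config()].
#' @param model Optional `cgan_model` to continue training; default fresh
#'   initialization from `config$seed`.
#' @param verbose Print one line per epoch.
#' @return A trained `cgan_model`; `model$log` holds per-epoch generator
#'   loss, discriminator loss, and test-set mean relative error. If a loss
#'   turns non-finite the run aborts and the last finite-epoch weights are
#'   returned (with a warning).
#' @export
train_cgan <- function(dataset, config = train_config(), model = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(dataset, "cceit_dataset"))
  tr <- which(dataset$split == "train")
  te <- which(dataset$split == "test")
  stopifnot(length(tr) >= 1, length(te) >= 1)
  if (is.null(model))
    model <- init_cgan(ncol(dataset$inputs), config, seed = config$seed)
  G <- model$G; D <- model$D
  opt_g <- list(); opt_d <- list()
  targets <- dataset$targets
  log <- data.frame()
  collapse_run <- 0L
  last_good <- list(G = G, D = D)
  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      X <- if (is.finite(config$noise_snr_db)) {
        dataset_inputs(dataset, config$noise_snr_db,
                       seed = child_seed(config$seed, 5000 + epoch))
      } else dataset$inputs
      ord <- sample(tr)
      nb <- ceiling(length(ord) / config$batch_size)
      gl <- dl <- 0
      for (b in seq_len(nb)) {
        rows <- ord[((b - 1) * config$batch_size + 1):
                      min(b * config$batch_size, length(ord))]
        if (length(rows) < 2) next
        x <- X[rows, , drop = FALSE]
        y_real <- targets[rows, , drop = FALSE]
        gf <- gen_forward(G, x, config, train = TRUE)
        G <- gf$G                               # running-stat update
        y_fake <- gf$y
        # --- discriminator step ---
        fr <- disc_forward(D, y_real, x, config)
        ff <- disc_forward(D, y_fake, x, config)
        nbatch <- length(rows)
        d_loss <- (bce_loss(fr$p, 1) + bce_loss(ff$p, 0)) / 2
        gr <- disc_backward(D, fr$cache, (fr$p - 1) / (2 * nbatch), config)
        gf2 <- disc_backward(D, ff$cache, (ff$p - 0) / (2 * nbatch), config)
        for (ly in names(D)) for (pn in c("W", "b")) {
          gsum <- gr$grads[[ly]][[pn]] + gf2$grads[[ly]][[pn]]
          key <- paste(ly, pn)
          st <- adam_step(D[[ly]][[pn]], gsum, opt_d[[key]], config$lr_d)
          D[[ly]][[pn]] <- st$p
          opt_d[[key]] <- st$state
        }
        # --- generator step (through the updated discriminator) ---
        fg <- disc_forward(D, y_fake, x, config)
        adv <- disc_backward(D, fg$cache, (fg$p - 1) / nbatch, config)
        l1_grad <- sign(y_fake - y_real) / length(y_real)
        dy <- adv$dimage + config$lambda_l1 * l1_grad
        g_loss <- bce_loss(fg$p, 1) +
          config$lambda_l1 * mean(abs(y_fake - y_real))
        grads <- gen_backward(G, gf$cache, dy, config)
        for (ly in names(grads)) for (pn in names(grads[[ly]])) {
          key <- paste(ly, pn)
          st <- adam_step(G[[ly]][[pn]], grads[[ly]][[pn]],
                          opt_g[[key]], config$lr_g)
          G[[ly]][[pn]] <- st$p
          opt_g[[key]] <- st$state
        }
        gl <- gl + g_loss / nb
        dl <- dl + d_loss / nb
      }
      if (!is.finite(gl) || !is.finite(dl)) {
        warning("training diverged at epoch ", epoch,
                "; returning last finite-epoch weights")
        G <- last_good$G; D <- last_good$D
        break
      }
      last_good <- list(G = G, D = D)
      model$G <- G; model$D <- D
      yh <- gen_forward(G, X[te, , drop = FALSE], config, train = FALSE)$y
      ie <- batch_ie(yh, targets[te, , drop = FALSE])
      log <- rbind(log, data.frame(epoch = epoch, g_loss = gl, d_loss = dl,
                                   test_ie = ie))
      collapse_run <- if (dl < 1e-4) collapse_run + 1L else 0L
      if (collapse_run == 3L)
        warning("discriminator loss collapsed towards zero for 3 epochs")
      if (verbose)
        message(sprintf("epoch %3d  g_loss %.4f  d_loss %.4f  test IE %.4f",
                        epoch, gl, dl, ie))
      if (!is.null(config$checkpoint_dir)) {
        dir.create(config$checkpoint_dir, showWarnings = FALSE,
                   recursive = TRUE)
        model$log <- log
        saveRDS(model, file.path(config$checkpoint_dir,
                                 sprintf("epoch_%03d.rds", epoch)))
        jsonlite::write_json(log, file.path(config$checkpoint_dir,
                                            "train_log.json"),
                             dataframe = "rows", auto_unbox = TRUE)
      }
    }
  })
  model$G <- G
  model$D <- D
  model$log <- log
  model
}
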