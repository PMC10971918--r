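# Neural-network primitives (exact layer equations) and the minimal
# dense-layer machinery, with hand-derived backpropagation and Adam.

#' Leaky rectified linear activation
#'
#' `LeakyReLU(x) = alpha * x` for `x < 0` and `x` otherwise.
#'
#' @param x Numeric vector/matrix.
#' @param alpha Negative-branch slope (>= 0); `alpha = 1` is the identity.
#' @return Same shape as `x`.
#' @export
#' @examples
#' leaky_relu(c(-2, 5), alpha = 0.1)  # -0.2, 5
leaky_relu <- function(x, alpha = 0.2) {
  stopifnot(alpha >= 0)
  ifelse(x < 0, alpha * x, x)
}

#' Affine (linear) layer
#'
#' `y = x W' + b` with learnable weights `W` (out x in) and bias `b`.
#'
#' @param x Input matrix (batch x in) or vector.
#' @param W Weight matrix (out x in).
#' @param b Bias vector (length out).
#' @return Output matrix (batch x out).
#' @export
linear_layer <- function(x, W, b) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != ncol(W)) stop("shape mismatch: input ", ncol(x),
                               " vs weights ", ncol(W))
  if (length(b) != nrow(W)) stop("shape mismatch: bias ", length(b),
                                 " vs weights ", nrow(W))
  sweep(x %*% t(W), 2, b, "+")
}

#' Batch normalization
#'
#' `y = (x - Mean[x]) / sqrt(Var[x] + eps) * W + b`, normalizing with the
#' supplied running statistics (inference mode) and then applying the
#' learnable per-feature scale `W` and shift `b`.
#'
#' @param x Input matrix (batch x features) or vector.
#' @param W,b Learnable scale and shift vectors (length features).
#' @param running_stats List with `mean` and `var` vectors.
#' @param eps Numerical-stability constant (> 0).
#' @return Normalized output, same shape as `x`.
#' @export
batch_norm <- function(x, W, b, running_stats, eps = 1e-5) {
  stopifnot(eps > 0)
  if (is.null(dim(x))) x <- matrix(x, 1)
  xhat <- sweep(sweep(x, 2, running_stats$mean),
                2, sqrt(running_stats$var + eps), "/")
  sweep(sweep(xhat, 2, W, "*"), 2, b, "+")
}

# --- internal training machinery -------------------------------------------

init_linear <- function(n_in, n_out, gain = sqrt(2)) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, gain / sqrt(n_in)),
                  n_out, n_in),
       b = numeric(n_out))
}

init_bn <- function(n) {
  list(g = rep(1, n), b = numeric(n),
       run_mean = numeric(n), run_var = rep(1, n))
}

# forward + cache for one linear layer
fwd_linear <- function(x, p) list(y = linear_layer(x, p$W, p$b), x = x)
bwd_linear <- function(dy, cache, p) {
  list(dx = dy %*% p$W,
       dW = t(dy) %*% cache$x,
       db = colSums(dy))
}

# batch-mode batch norm (uses batch statistics, updates running stats)
fwd_bn_train <- function(x, p, eps, momentum = 0.1) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  y <- sweep(sweep(xhat, 2, p$g, "*"), 2, p$b, "+")
  p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
  p$run_var <- (1 - momentum) * p$run_var + momentum * v
  list(y = y, xhat = xhat, istd = istd, p = p)
}
bwd_bn <- function(dy, cache, p) {
  n <- nrow(dy)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, p$g, "*")
  dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
                sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*"),
              2, cache$istd, "*")
  list(dx = dx, dg = dg, db = db)
}

fwd_lrelu <- function(x, alpha) list(y = leaky_relu(x, alpha), x = x)
bwd_lrelu <- function(dy, cache, alpha) dy * ifelse(cache$x < 0, alpha, 1)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Adam update; state carries first/second moments and the step counter.
adam_step <- function(p, grad, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state)) state <- list(m = p * 0, v = p * 0, t = 0)
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), state = state)
}
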