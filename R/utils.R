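# Internal helpers: local RNG scoping and reproducible child streams.

# Evaluate `expr` under a locally-set seed without disturbing the caller's
# RNG state. If seed is NULL the expression runs under the current stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize a stream so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed
#'
#' Datasets are generated from one root seed with an independent child stream
#' per sample index, so samples are reproducible individually and independent
#' of generation order. The derivation is a fixed integer hash kept inside
#' 32-bit range.
#'
#' @param root_seed Integer root seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed.
#' @export
child_seed <- function(root_seed, index) {
  stopifnot(is.numeric(root_seed), is.numeric(index), index >= 0)
  # Weyl-style mixing; doubles hold these products exactly (< 2^53)
  h <- (abs(root_seed) %% 2147483647) * 48271 + (index + 1) * 16807
  h <- h %% 2147483647
  as.integer(h)
}

# mean +/- half-range draw: truncated normal (sd = hr/2, truncated at the
# range ends) or uniform, vectorized over n.
draw_ranged <- function(n, mean, hr, law = c("truncnorm", "uniform")) {
  law <- match.arg(law)
  if (hr < 0) stop("half-range must be >= 0")
  if (hr == 0) return(rep(mean, n))
  if (law == "uniform") return(stats::runif(n, mean - hr, mean + hr))
  out <- stats::rnorm(n, mean, hr / 2)
  bad <- which(out < mean - hr | out > mean + hr)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, hr / 2)
    bad <- bad[out[bad] < mean - hr | out[bad] > mean + hr]
  }
  out
}

in_range <- function(x, mean, hr) x >= mean - hr & x <= mean + hr

`%||%` <- function(a, b) if (is.null(a)) b else a
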