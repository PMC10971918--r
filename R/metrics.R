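# Image-quality metrics for normalized reconstruction images and their
# aggregation over evaluation sets.

#' Root mean square error
#'
#' `RMSE = sqrt(mean((y - yhat)^2))` over all pixels.
#'
#' @param yhat,y Numeric vectors or matrices of equal length (reconstruction
#'   and reference).
#' @return Non-negative scalar.
#' @export
#' @examples
#' rmse(c(3, 4), c(0, 0))  # sqrt(25 / 2)
rmse <- function(yhat, y) {
  if (length(yhat) != length(y)) stop("length mismatch")
  sqrt(mean((as.numeric(y) - as.numeric(yhat))^2))
}

#' Two-dimensional correlation coefficient
#'
#' Pearson correlation of the flattened images.
#'
#' @param yhat,y Numeric vectors or matrices of equal length; both must be
#'   non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
corr2d <- function(yhat, y) {
  if (length(yhat) != length(y)) stop("length mismatch")
  yhat <- as.numeric(yhat); y <- as.numeric(y)
  if (stats::sd(yhat) == 0 || stats::sd(y) == 0)
    stop("zero-variance image: correlation undefined")
  stats::cor(yhat, y)
}

#' Peak signal-to-noise ratio
#'
#' The form used for the reported image-quality tables:
#' `PSNR = 10 log10( N * max(yhat) / sum((y - yhat)^2) )`,
#' with `N` the pixel count. Note this references the peak of the
#' reconstruction linearly; the conventional definition
#' `10 log10(max(yhat)^2 / MSE)` is available with
#' `conventional = TRUE`.
#'
#' @param yhat,y Numeric vectors or matrices of equal length.
#' @param conventional Use the conventional peak-squared/MSE form.
#' @return PSNR in dB; `Inf` for a perfect match.
#' @export
#' @examples
#' psnr(rep(1, 4), rep(1, 4) + c(0.1, -0.1, 0.1, -0.1))  # 10 log10(100)
psnr <- function(yhat, y, conventional = FALSE) {
  if (length(yhat) != length(y)) stop("length mismatch")
  yhat <- as.numeric(yhat); y <- as.numeric(y)
  sse <- sum((y - yhat)^2)
  if (sse == 0) return(Inf)
  if (conventional) {
    10 * log10(max(yhat)^2 / (sse / length(y)))
  } else {
    10 * log10(length(y) * max(yhat) / sse)
  }
}

#' Global structural similarity index
#'
#' Single-window SSIM over the whole image:
#' `SSIM = (2 mu_y mu_yhat + c1)(2 cov + c2) /
#'   ((mu_y^2 + mu_yhat^2 + c1)(var_y + var_yhat + c2))`,
#' with stabilizers `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` for dynamic range
#' `L` (1 for normalized images).
#'
#' @param yhat,y Numeric vectors or matrices of equal length.
#' @param c1,c2 Stabilization constants.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim_global <- function(yhat, y, c1 = 0.01^2, c2 = 0.03^2) {
  if (length(yhat) != length(y)) stop("length mismatch")
  yhat <- as.numeric(yhat); y <- as.numeric(y)
  n <- length(y)
  mu_y <- mean(y); mu_h <- mean(yhat)
  v_y <- mean((y - mu_y)^2)
  v_h <- mean((yhat - mu_h)^2)
  cov <- mean((y - mu_y) * (yhat - mu_h))
  ((2 * mu_y * mu_h + c1) * (2 * cov + c2)) /
    ((mu_y^2 + mu_h^2 + c1) * (v_y + v_h + c2))
}

#' Evaluate reconstructions over a sample set and noise levels
#'
#' Computes the four image-quality metrics (RMSE, PSNR, SSIM, 2D
#' correlation) for every test-split sample of a dataset at each requested
#' measurement SNR, reconstructing with either a trained model or a
#' supplied reconstruction function. Means and standard deviations per
#' metric and SNR are reported together with per-sample values and
#' histogram bin counts.
#'
#' @param model A `cgan_model`, or a function `f(inputs)` mapping a matrix
#'   of standardized inputs (n x input_len) to an n x 4096 image matrix
#'   (e.g. a baseline reconstructor).
#' @param dataset A `cceit_dataset`.
#' @param snr_levels Numeric vector of peak SNRs in dB (default 60, 30, 10).
#' @param rows Sample rows to evaluate (default: the test split).
#' @param seed Seed for the evaluation noise draws.
#' @param breaks Histogram bin count per metric.
#' @return A `metrics_report`: list with `summary` (data.frame of mean/sd
#'   per metric and SNR), `per_sample` (data.frame), and `histograms`.
#' @export
evaluate_set <- function(model, dataset, snr_levels = c(60, 30, 10),
                         rows = NULL, seed = 1, breaks = 30) {
  stopifnot(inherits(dataset, "cceit_dataset"))
  rows <- rows %||% which(dataset$split == "test")
  if (length(rows) == 0) stop("empty evaluation set")
  recon <- if (inherits(model, "cgan_model")) {
    function(X) generator_forward(model, X)
  } else {
    stopifnot(is.function(model))
    model
  }
  per <- data.frame()
  failures <- 0L
  for (li in seq_along(snr_levels)) {
    snr <- snr_levels[li]
    X <- dataset_inputs(dataset, snr, seed = child_seed(seed, li),
                        rows = rows)
    Y <- recon(X)
    for (k in seq_along(rows)) {
      y <- dataset$targets[rows[k], ]
      yh <- Y[k, ]
      m <- tryCatch(
        data.frame(snr_db = snr, sample = rows[k],
                   rmse = rmse(yh, y), psnr = psnr(yh, y),
                   ssim = ssim_global(yh, y), cc2d = corr2d(yh, y)),
        error = function(e) NULL)
      if (is.null(m)) failures <- failures + 1L else per <- rbind(per, m)
    }
  }
  # PSNR is +Inf on perfect matches; aggregate over the finite values and
  # report the sentinel when every sample is perfect
  fin_mean <- function(v) if (any(is.finite(v))) mean(v[is.finite(v)]) else Inf
  fin_sd <- function(v) if (sum(is.finite(v)) > 1) stats::sd(v[is.finite(v)]) else 0
  agg <- do.call(rbind, lapply(split(per, per$snr_db), function(d) {
    data.frame(snr_db = d$snr_db[1],
               metric = c("rmse", "psnr", "ssim", "cc2d"),
               mean = c(mean(d$rmse), fin_mean(d$psnr),
                        mean(d$ssim), mean(d$cc2d)),
               sd = c(stats::sd(d$rmse), fin_sd(d$psnr),
                      stats::sd(d$ssim), stats::sd(d$cc2d)))
  }))
  rownames(agg) <- NULL
  hists <- lapply(split(per, per$snr_db), function(d) {
    lapply(d[c("rmse", "psnr", "ssim", "cc2d")], function(v) {
      v <- v[is.finite(v)]
      if (length(v) == 0) return(NULL)
      graphics::hist(v, breaks = breaks, plot = FALSE)[c("breaks", "counts")]
    })
  })
  structure(list(summary = agg, per_sample = per, histograms = hists,
                 failures = failures, n = length(rows)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", x$n, "samples\n")
  s <- x$summary
  for (snr in unique(s$snr_db)) {
    d <- s[s$snr_db == snr, ]
    cat(sprintf("  SNR %4s dB:  %s\n", format(snr), paste(
      sprintf("%s %.3f+/-%.3f", d$metric, d$mean, d$sd), collapse = "  ")))
  }
  invisible(x)
}

#' Export a metrics report
#'
#' Writes the summary as JSON and the per-sample metrics as CSV; histogram
#' PNGs are written when the `png` device is usable.
#'
#' @param report A `metrics_report`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
export_metrics <- function(report, dir) {
  stopifnot(inherits(report, "metrics_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$summary, file.path(dir, "metrics_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(report$per_sample, file.path(dir, "metrics_per_sample.csv"),
                   row.names = FALSE)
  for (snr in names(report$histograms)) {
    ok <- tryCatch({
      grDevices::png(file.path(dir, paste0("hist_snr_", snr, ".png")),
                     width = 900, height = 700)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) break
    graphics::par(mfrow = c(2, 2))
    h <- report$histograms[[snr]]
    for (m in names(h)) {
      mids <- (h[[m]]$breaks[-1] + h[[m]]$breaks[-length(h[[m]]$breaks)]) / 2
      graphics::plot(mids, h[[m]]$counts, type = "h", lwd = 4,
                     main = paste(toupper(m), "at", snr, "dB"),
                     xlab = m, ylab = "count")
    }
    grDevices::dev.off()
  }
  invisible(dir)
}
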