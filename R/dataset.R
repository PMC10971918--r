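# Dataset orchestration: phantom sampling, forward simulation,
# standardization, condition labelling, train/test splitting, persistence.

CONDITIONS <- c("healthy", "hemorrhagic", "ischemic")

#' Draw patient condition labels
#'
#' Uniform draws over the three modelled conditions (healthy, hemorrhagic
#' stroke, ischemic stroke).
#'
#' @param n Number of labels.
#' @param seed Optional integer seed.
#' @return Character vector of length `n`.
#' @export
#' @examples
#' table(draw_condition(1000, seed = 1))
draw_condition <- function(n = 1, seed = NULL) {
  with_local_seed(seed, sample(CONDITIONS, n, replace = TRUE))
}

# Normalize a conductivity map to [0, 1] over the head support; background
# pixels stay at 0.
normalize_target <- function(sigma, labels) {
  support <- labels > 0L
  v <- sigma[support]
  rng <- range(v)
  out <- matrix(0, nrow(sigma), ncol(sigma))
  if (diff(rng) > 0) out[support] <- (v - rng[1]) / (rng[2] - rng[1])
  out
}

# Generate one dataset sample: geometry -> properties -> optional stroke ->
# 64 x 64 target and clean measurement frame on the solver grid.
generate_sample <- function(seed, condition, approach, tables, sensor,
                            sgrid, base_geom = NULL, relative_sd = 0.05,
                            subsample = 1) {
  geom <- if (approach == "constraint") {
    sample_geometry(tables, seed = child_seed(seed, 1))
  } else {
    perturb_geometry(base_geom, tables, relative_sd = relative_sd,
                     seed = child_seed(seed, 1))
  }
  props <- assign_region_properties(seed = child_seed(seed, 2))
  ph <- build_healthy_phantom(geom, props)
  if (condition != "healthy")
    ph <- insert_stroke(ph, condition, seed = child_seed(seed, 3))
  field <- permittivity_field(ph, sgrid, sensor$frequency_Hz,
                              subsample = subsample)
  frame <- measure_frame(field, sensor)
  list(frame = frame$values,
       target = normalize_target(ph$sigma, ph$labels),
       sigma_max = max(ph$sigma), condition = condition,
       params = unlist(geom$params), seed = seed)
}

#' Build a simulated CCEIT dataset
#'
#' Generates labelled samples with both generation approaches
#' (constraint-based sampling and perturbation of frozen base models),
#' simulates the complex capacitance frames, splits into training and
#' testing parts, and standardizes the network inputs. Inputs are the real
#' and imaginary measurement components stacked into a `2 x M` frame
#' (flattened to length `2 M`); targets are `64 x 64` conductivity images
#' normalized to `[0, 1]` over the head support.
#'
#' Measurement noise at `snr_db` peak SNR is applied once per sample to form
#' the default training inputs; the clean frames are kept so evaluation can
#' re-noise them at other SNR levels ([dataset_inputs()]).
#' Standardization constants (per-channel mean and standard deviation) are
#' computed on the training split only.
#'
#' @param n_constraint,n_perturb Sample counts for the two approaches.
#' @param tables Constraint tables (default packaged set).
#' @param sensor A [sensor_model()].
#' @param solver_n Solver grid resolution (default 64).
#' @param snr_db Peak SNR of the per-sample measurement noise (default 30;
#'   `Inf` for clean).
#' @param seed Root seed; every sample derives an independent child stream,
#'   so the dataset is reproducible and order-independent.
#' @param split_ratio Training fraction of the train/test partition
#'   (default 0.75).
#' @param n_bases Number of frozen base geometries for the perturbation
#'   approach (default 50).
#' @param relative_sd Perturbation strength for the second approach.
#' @param subsample Material supersampling factor for the solver field.
#' @param progress Print progress every 500 samples.
#' @return A `cceit_dataset`: matrices `inputs` (n x 2M, standardized,
#'   noisy), `inputs_raw` (clean, unstandardized), `targets` (n x 4096),
#'   `labels`, `approach`, `split`, standardization constants `std`, and
#'   `manifest`.
#' @export
build_dataset <- function(n_constraint, n_perturb, tables = NULL,
                          sensor = sensor_model(), solver_n = 64,
                          snr_db = 30, seed = 1, split_ratio = 0.75,
                          n_bases = 50, relative_sd = 0.05, subsample = 1,
                          progress = FALSE) {
  stopifnot(n_constraint + n_perturb >= 1)
  tables <- tables %||% load_constraint_tables()
  sgrid <- solver_grid(sensor, solver_n)
  n <- n_constraint + n_perturb
  # frozen base models for the perturbation approach
  bases <- NULL
  if (n_perturb > 0) {
    bases <- lapply(seq_len(n_bases), function(k)
      sample_geometry(tables, seed = child_seed(seed, 900000 + k)))
  }
  ne <- sensor$n_electrodes
  m <- ne * (ne - 1)
  inputs_raw <- matrix(NA_real_, n, 2 * m)
  targets <- matrix(NA_real_, n, 64 * 64)
  labels <- character(n)
  approach <- rep(c("constraint", "perturbation"), c(n_constraint, n_perturb))
  params <- vector("list", n)
  seeds <- integer(n)
  failures <- 0L
  conditions <- draw_condition(n, seed = child_seed(seed, 999999))
  for (i in seq_len(n)) {
    base <- if (approach[i] == "perturbation") {
      k <- 1 + (child_seed(seed, 800000 + i) %% n_bases)
      bases[[k]]
    }
    for (attempt in 0:19) {
      si <- child_seed(seed, i + attempt * 1000000)
      res <- tryCatch(
        generate_sample(si, conditions[i], approach[i], tables, sensor,
                        sgrid, base, relative_sd, subsample),
        error = function(e) NULL)
      if (!is.null(res)) break
      failures <- failures + 1L
    }
    if (is.null(res)) stop("sample ", i, " failed repeatedly")
    inputs_raw[i, ] <- c(Re(res$frame), Im(res$frame))
    targets[i, ] <- as.vector(res$target)
    labels[i] <- res$condition
    params[[i]] <- res$params
    seeds[i] <- res$seed
    if (progress && i %% 500 == 0) message("generated ", i, "/", n)
  }
  sp <- split_train_test(n, split_ratio, seed = child_seed(seed, 999998))
  split <- character(n)
  split[sp$train] <- "train"
  split[sp$test] <- "test"
  # noise once per sample, then standardization from the clean train inputs
  noisy <- add_input_noise(inputs_raw, snr_db, seed = child_seed(seed, 999997))
  std <- list(mean = colMeans(inputs_raw[sp$train, , drop = FALSE]),
              sd = apply(inputs_raw[sp$train, , drop = FALSE], 2, stats::sd))
  std$sd[std$sd == 0 | !is.finite(std$sd)] <- 1
  inputs <- sweep(sweep(noisy, 2, std$mean), 2, std$sd, "/")
  manifest <- list(
    n = n, n_constraint = n_constraint, n_perturb = n_perturb,
    counts = as.list(table(labels)), snr_db = snr_db, root_seed = seed,
    split_ratio = split_ratio, solver_n = solver_n, subsample = subsample,
    n_bases = n_bases, relative_sd = relative_sd, failures = failures,
    n_electrodes = ne, frame_length = m, target_px = 64L)
  structure(list(inputs = inputs, inputs_raw = inputs_raw, targets = targets,
                 labels = labels, approach = approach, split = split,
                 std = std, params = params, seeds = seeds,
                 manifest = manifest, sensor = sensor),
            class = "cceit_dataset")
}

#' @export
print.cceit_dataset <- function(x, ...) {
  m <- x$manifest
  cat("<cceit_dataset>", m$n, "samples (", m$n_constraint, "constraint +",
      m$n_perturb, "perturbation );", sum(x$split == "train"), "train /",
      sum(x$split == "test"), "test\n")
  cat("  conditions:", paste(names(m$counts), unlist(m$counts),
                             collapse = ", "), "\n")
  invisible(x)
}

# Per-sample peak-referenced complex noise on raw (Re | Im) input rows.
add_input_noise <- function(inputs_raw, snr_db, seed = NULL) {
  if (is.infinite(snr_db)) return(inputs_raw)
  m <- ncol(inputs_raw) / 2
  with_local_seed(seed, {
    peak <- apply(inputs_raw, 1, function(r)
      max(sqrt(r[1:m]^2 + r[m + 1:m]^2)))
    sd <- peak / 10^(snr_db / 20)
    inputs_raw + matrix(stats::rnorm(length(inputs_raw)),
                        nrow(inputs_raw)) * sd
  })
}

#' Standardized network inputs at a chosen noise level
#'
#' Re-noises the clean measurement frames of a dataset at the requested
#' peak SNR and applies the dataset's (train-split) standardization.
#'
#' @param dataset A `cceit_dataset`.
#' @param snr_db Peak SNR in dB (`Inf` = clean).
#' @param seed Optional seed for the noise draw.
#' @param rows Optional row subset.
#' @return Matrix of standardized inputs.
#' @export
dataset_inputs <- function(dataset, snr_db = Inf, seed = NULL, rows = NULL) {
  stopifnot(inherits(dataset, "cceit_dataset"))
  raw <- dataset$inputs_raw
  if (!is.null(rows)) raw <- raw[rows, , drop = FALSE]
  noisy <- add_input_noise(raw, snr_db, seed = seed)
  sweep(sweep(noisy, 2, dataset$std$mean), 2, dataset$std$sd, "/")
}

#' Random train/test partition
#'
#' Splits `n` samples at the configured ratio (exact up to one sample) into
#' disjoint, covering index sets.
#'
#' @param n Number of samples (or an object with one sample per row).
#' @param ratio Training fraction in (0, 1).
#' @param seed Optional seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
#' @examples
#' sp <- split_train_test(1000, 0.75, seed = 1)
#' length(sp$train)  # 750
split_train_test <- function(n, ratio = 0.75, seed = NULL) {
  if (!is.numeric(n)) n <- nrow(n)
  stopifnot(n >= 2, ratio > 0, ratio < 1)
  n_train <- max(1L, min(n - 1L, round(n * ratio)))
  with_local_seed(seed, {
    train <- sort(sample.int(n, n_train))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Save / load a dataset container
#'
#' Persists the dataset as a serialized container plus a JSON manifest.
#'
#' @param dataset A `cceit_dataset`.
#' @param dir Output directory (created if needed).
#' @return `save_dataset` invisibly returns the directory; `load_dataset`
#'   returns the `cceit_dataset`.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cceit_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(dataset, file.path(dir, "dataset.rds"))
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  ds <- readRDS(file.path(dir, "dataset.rds"))
  stopifnot(inherits(ds, "cceit_dataset"))
  ds
}
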