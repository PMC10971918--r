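# Pipeline orchestration: configuration, staged execution with caching, and
# provenance records. Wires dataset generation, the linear baseline, network
# training, and evaluation into one reproducible run.

#' Load or build a run configuration
#'
#' A run configuration collects all module settings (dataset sizes, solver
#' grid, sensor parameters, training parameters, evaluation SNR levels), a
#' root seed, and the output directory. Settings omitted from the file or
#' list take the package defaults (a desk-scale run: 2000 + 2000 training
#' samples; the full-scale sizes of the study are reached by raising the
#' dataset counts).
#'
#' @param path Optional YAML file with configuration overrides.
#' @param overrides Optional named list of overrides (applied after the
#'   file).
#' @return A validated `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    seed = 1,
    out_dir = "cceit_run",
    dataset = list(n_constraint = 2000, n_perturb = 2000, snr_db = 30,
                   solver_n = 64, split_ratio = 0.75, n_bases = 50,
                   relative_sd = 0.05, subsample = 1),
    sensor = list(n_electrodes = 16, insulation_mm = 4, eps_insulation = 4,
                  coverage = 0.8, screen_gap_mm = 20),
    train = list(epochs = 100, lr_g = 1e-3, lr_d = 1e-8, batch_size = 64,
                 lambda_l1 = 100, noise_snr_db = 30,
                 hidden_g = c(512, 512), hidden_d = c(128, 32)),
    evaluate = list(snr_levels = c(60, 30, 10)),
    baseline = list(truncation = NA),
    tables = NULL)
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_in(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge_in(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_in(cfg, overrides)
  stopifnot(cfg$dataset$n_constraint + cfg$dataset$n_perturb >= 1,
            cfg$train$epochs >= 1)
  class(cfg) <- "run_config"
  cfg
}

config_json <- function(x) {
  as.character(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA))
}

# Run a pipeline stage unless its artifact exists with an identical config
# fingerprint (content-keyed caching per stage).
stage <- function(name, dir, key, artifact, fn, quiet = FALSE) {
  fp <- file.path(dir, paste0(name, ".config.json"))
  art <- file.path(dir, artifact)
  if (file.exists(art) && file.exists(fp) &&
      identical(readLines(fp, warn = FALSE), key)) {
    if (!quiet) message("[", name, "] cached")
    return(readRDS(art))
  }
  if (!quiet) message("[", name, "] running")
  out <- tryCatch(fn(), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  saveRDS(out, art)
  writeLines(key, fp)
  out
}

#' Run the full simulation / training / evaluation pipeline
#'
#' Executes the stages generate (dataset simulation), baseline (sensitivity
#' matrix), train (adversarial reconstructor), and evaluate (image-quality
#' metrics for the trained model and the LBP baseline) in order, caching
#' each stage on disk keyed by its configuration section. A completed run
#' directory holds the dataset container, the sensitivity operator, the
#' trained model with its training log, metric reports, and the exact
#' configuration.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the dataset, sensitivity matrix, model,
#'   and metric reports.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(config_json(config), file.path(config$out_dir, "config.json"))
  sensor <- do.call(sensor_model, config$sensor)
  tables <- if (is.null(config$tables)) load_constraint_tables()
            else load_constraint_tables(config$tables)
  dcfg <- config$dataset
  ds <- stage("generate", config$out_dir,
              config_json(c(dcfg, seed = config$seed, config$sensor)),
              "dataset.rds", function() {
    build_dataset(dcfg$n_constraint, dcfg$n_perturb, tables = tables,
                  sensor = sensor, solver_n = dcfg$solver_n,
                  snr_db = dcfg$snr_db, seed = config$seed,
                  split_ratio = dcfg$split_ratio, n_bases = dcfg$n_bases,
                  relative_sd = dcfg$relative_sd,
                  subsample = dcfg$subsample, progress = !quiet)
  }, quiet = quiet)
  S <- stage("baseline", config$out_dir,
             config_json(c(config$sensor, solver_n = dcfg$solver_n)),
             "sensitivity.rds", function() {
    sg <- solver_grid(sensor, dcfg$solver_n)
    pri <- region_priors()
    ref <- uniform_field(sg, eps_r = pri$eps_mean[pri$region == "brain"],
                         sigma_mS_m = pri$sigma_mean[pri$region == "brain"],
                         head_only = TRUE, frequency_Hz = sensor$frequency_Hz,
                         belt_semi_x = sensor$belt_semi_x,
                         belt_semi_y = sensor$belt_semi_y)
    sensitivity_matrix(sensor, ref)
  }, quiet = quiet)
  tcfg <- config$train
  model <- stage("train", config$out_dir,
                 config_json(c(tcfg, seed = config$seed, dcfg)),
                 "model.rds", function() {
    cfg <- train_config(lr_g = tcfg$lr_g, lr_d = tcfg$lr_d,
                        epochs = tcfg$epochs, batch_size = tcfg$batch_size,
                        lambda_l1 = tcfg$lambda_l1,
                        noise_snr_db = tcfg$noise_snr_db,
                        hidden_g = tcfg$hidden_g, hidden_d = tcfg$hidden_d,
                        seed = config$seed)
    train_cgan(ds, cfg, verbose = !quiet)
  }, quiet = quiet)
  reports <- stage("evaluate", config$out_dir,
                   config_json(c(config$evaluate, seed = config$seed)),
                   "metrics.rds", function() {
    lbp_fun <- baseline_reconstructor(S, ds)
    list(model = evaluate_set(model, ds, config$evaluate$snr_levels,
                              seed = config$seed),
         lbp = evaluate_set(lbp_fun, ds, config$evaluate$snr_levels,
                            seed = config$seed))
  }, quiet = quiet)
  export_metrics(reports$model, file.path(config$out_dir, "metrics_model"))
  export_metrics(reports$lbp, file.path(config$out_dir, "metrics_lbp"))
  invisible(list(dataset = ds, sensitivity = S, model = model,
                 reports = reports))
}

#' Baseline reconstruction function for evaluation
#'
#' Wraps the LBP baseline as a batch reconstructor operating on the same
#' standardized inputs as the network: inputs are de-standardized back to
#' raw capacitance frames, the mean training frame serves as the reference
#' measurement, and each LBP image is min-max normalized to `[0, 1]` for
#' comparison against the normalized targets.
#'
#' @param S A [sensitivity_matrix()].
#' @param dataset The `cceit_dataset` whose standardization applies.
#' @return A function mapping an n x input_len matrix to n x 4096 images.
#' @export
baseline_reconstructor <- function(S, dataset) {
  stopifnot(inherits(S, "sensitivity_matrix"),
            inherits(dataset, "cceit_dataset"))
  m <- dataset$manifest$frame_length
  ref_raw <- colMeans(dataset$inputs_raw[dataset$split == "train", ,
                                         drop = FALSE])
  support <- colSums(abs(S$S)) > 0   # pixels the operator can see (head)
  function(X) {
    raw <- sweep(sweep(X, 2, dataset$std$sd, "*"), 2, dataset$std$mean, "+")
    out <- matrix(0, nrow(raw), S$image_grid$n^2)
    for (i in seq_len(nrow(raw))) {
      dc <- (raw[i, m + 1:m] - ref_raw[m + 1:m])  # imaginary part change
      img <- as.vector(lbp_reconstruct(dc, S))
      v <- img[support]
      rng <- range(v)
      if (diff(rng) > 0) img[support] <- (v - rng[1]) / diff(rng)
      img[!support] <- 0
      out[i, ] <- img
    }
    out
  }
}
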