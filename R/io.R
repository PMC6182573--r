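#' Write epoched signals to a directory of per-trial TSV files
#'
#' One `trial_XXXX.tsv` per epoch (samples in rows, channels in columns,
#' header = channel ids) plus a `meta.json` with the sampling rate and
#' geometry. Values are written in full double precision, so a round trip
#' reproduces them exactly.
#'
#' @param x an [epoched_signals].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epochs_tsv <- function(x, dir) {
  stopifnot(inherits(x, "epoched_signals"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(fs = x$fs, channel_ids = x$channel_ids,
         n_trials = n_trials(x), n_samples = n_samples(x)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  for (tr in seq_len(n_trials(x))) {
    m <- t(matrix(x$data[tr, , ], nrow = n_channels(x)))
    colnames(m) <- x$channel_ids
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       file.path(dir, sprintf("trial_%04d.tsv", tr)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read epoched signals from a per-trial TSV directory
#'
#' @param dir a directory written by [write_epochs_tsv()].
#' @return An [epoched_signals].
#' @export
read_epochs_tsv <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^trial_\\d+\\.tsv$", full.names = TRUE))
  if (length(files) != meta$n_trials)
    stop("expected ", meta$n_trials, " trial files, found ", length(files))
  dat <- array(0, c(meta$n_trials, length(meta$channel_ids), meta$n_samples))
  for (i in seq_along(files)) {
    m <- as.matrix(utils::read.delim(files[i], check.names = FALSE))
    dat[i, , ] <- t(m)
  }
  epoched_signals(dat, fs = meta$fs, channel_ids = meta$channel_ids)
}

#' Export a curve (measure or threshold) as TSV
#'
#' Measure curves get columns `freq_hz`, `value`; cross-spectra get
#' `freq_hz`, `re`, `im`; thresholds get `freq_hz`, `upper`, `lower`.
#'
#' @param x an `fc_curve`, `cross_spectrum`, or `surrogate_threshold`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(x, path) {
  df <- if (inherits(x, "fc_curve")) {
    data.frame(freq_hz = x$freqs, value = x$values)
  } else if (inherits(x, "cross_spectrum")) {
    data.frame(freq_hz = x$freqs, re = Re(x$S_uv), im = Im(x$S_uv))
  } else if (inherits(x, "surrogate_threshold")) {
    data.frame(freq_hz = x$freqs, upper = x$upper, lower = x$lower)
  } else stop("unsupported object for TSV export")
  utils::write.table(format(df, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an FC map as a TSV edge list
#'
#' Columns `sensor_a`, `sensor_b`, `weight` over the upper triangle.
#'
#' @param map an `fc_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fc_map_tsv <- function(map, path) {
  ed <- map_edges(map)
  labs <- rownames(map)
  out <- data.frame(sensor_a = labs[ed$a], sensor_b = labs[ed$b], weight = ed$w)
  utils::write.table(format(out, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a ROC result as TSV plus a JSON summary
#'
#' @param roc a `roc_result`.
#' @param path_tsv TSV path (`m`, `TP`, `FP`, `TPR`, `FPR`).
#' @param path_json optional JSON path for the AUC summary.
#' @return `path_tsv`, invisibly.
#' @export
write_roc_tsv <- function(roc, path_tsv, path_json = NULL) {
  stopifnot(inherits(roc, "roc_result"))
  utils::write.table(
    data.frame(m = roc$m, TP = roc$TP, FP = roc$FP, TPR = roc$TPR, FPR = roc$FPR),
    path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(list(auc = roc$auc, K = roc$K), path_json,
                         auto_unbox = TRUE, digits = NA)
  invisible(path_tsv)
}

#' Run a self-contained bivariate scenario and write its artifact bundle
#'
#' Simulates a two-source scenario, mixes it into two sensors, computes the
#' requested measure curves and their surrogate thresholds, and writes
#' everything (per-curve TSVs, thresholds, the resolved configuration and a
#' line-JSON log) into `out_dir`. Fully deterministic given `config$seed`.
#'
#' @param config a named list (or a path to a JSON/YAML file holding one)
#'   with elements: `model` (`"mvar"`, `"nmm"`, or `"bandlimited"`),
#'   `seed`, `measures` (default all nine), `n_trials`, `epoch_s`, `fs`,
#'   and model-specific fields: `delay` (samples for mvar/bandlimited, ms
#'   for nmm), `coupling`, `bandwidth`, `beta`, `n_surrogates`.
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the curves, thresholds, and file paths.
#' @export
run_scenario <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  defaults <- list(model = "mvar", seed = 1, measures = FC_MEASURES,
                   n_trials = 100, epoch_s = 1, fs = 250, delay = 3,
                   coupling = 0.5, bandwidth = 2, beta = 0.9,
                   n_surrogates = 200)
  unknown <- setdiff(names(config), c(names(defaults), "label"))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  if (!cfg$model %in% c("mvar", "nmm", "bandlimited"))
    stop("config error: model must be mvar, nmm or bandlimited")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n_samples <- round(cfg$epoch_s * cfg$fs)
  log_path <- file.path(out_dir, "log.jsonl")
  logf <- file(log_path, "w")
  on.exit(close(logf))
  log_line <- function(...) {
    writeLines(jsonlite::toJSON(list(...), auto_unbox = TRUE), logf)
  }
  log_line(event = "start", model = cfg$model, seed = cfg$seed)

  sens <- switch(cfg$model,
    mvar = {
      net <- fc_network(data.frame(from = 2, to = 1, C = cfg$coupling,
                                   delay = cfg$delay),
                        n_roi = 2, kind = "mvar")
      src <- simulate_mvar(net, cfg$n_trials, n_samples, cfg$fs,
                           seed = derive_seed(cfg$seed, "sim"))
      mix_two_sensors(src, seed = derive_seed(cfg$seed, "sensor-noise"))
    },
    nmm = {
      net <- fc_network(data.frame(from = 2, to = 1, C = cfg$coupling,
                                   delay = cfg$delay),
                        n_roi = 2, kind = "nmm")
      src <- simulate_nmm_sdde(net, cfg$n_trials, cfg$epoch_s, cfg$fs,
                               seed = derive_seed(cfg$seed, "sim"))
      mix_two_sensors(src, seed = derive_seed(cfg$seed, "sensor-noise"))
    },
    bandlimited = simulate_bandlimited_pair(
      bandwidth = cfg$bandwidth, delay = cfg$delay, beta = cfg$beta,
      n_trials = cfg$n_trials, n_samples = n_samples, fs = cfg$fs,
      seed = derive_seed(cfg$seed, "sim"))
  )
  spec <- epoch_fft(center_epochs(sens))
  curves <- list(); thresholds <- list()
  for (msr in cfg$measures) {
    msr <- match_measure(msr)
    curves[[msr]] <- measure_curve(spec, "u", "v", msr, warn = FALSE)
    thresholds[[msr]] <- surrogate_threshold(
      spec, "u", "v", msr, n_surrogates = cfg$n_surrogates,
      seed = derive_seed(cfg$seed, paste0("surrogates/", msr)))
    write_curve_tsv(curves[[msr]],
                    file.path(out_dir, paste0("fc_", tolower(msr), ".tsv")))
    write_curve_tsv(thresholds[[msr]],
                    file.path(out_dir, paste0("threshold_", tolower(msr), ".tsv")))
    log_line(event = "measure", measure = msr,
             peak_hz = curves[[msr]]$freqs[which.max(abs(curves[[msr]]$values))])
  }
  jsonlite::write_json(cfg, file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(event = "done")
  invisible(list(config = cfg, curves = curves, thresholds = thresholds,
                 out_dir = out_dir))
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Small deterministic fixtures for examples and tests
#'
#' @param seed integer seed.
#' @return A list: `ar_pair` (2-channel, 8-trial coupled AR epochs),
#'   `toy_layout` (6-sensor, 2-ROI [synth_layout()]), and `spectral_toy`
#'   (3-trial, 2-channel, 8-bin `spectral_ensemble` with pseudo-random
#'   complex coefficients).
#' @export
make_fixtures <- function(seed = 1) {
  ar_pair <- simulate_mvar(
    fc_network(data.frame(from = 2, to = 1, C = 0.5, delay = 3),
               n_roi = 2, kind = "mvar"),
    n_trials = 8, n_samples = 64, fs = 250,
    seed = derive_seed(seed, "fixture-ar"))
  toy_layout <- synth_layout(n_sensors = 6, n_background = 10,
                             roi_positions = rbind(c(-0.5, 0.3, 0.4),
                                                   c(0.5, -0.2, 0.4)),
                             seed = derive_seed(seed, "fixture-layout"))
  co <- with_seed(derive_seed(seed, "fixture-spec"), {
    array(complex(real = rnorm(3 * 2 * 8), imaginary = rnorm(3 * 2 * 8)),
          c(3, 2, 8))
  })
  spectral_toy <- structure(
    list(coeffs = co, freqs = 0:7, fs = 16, n_trials = 3L, nt = 15L,
         channel_ids = c("u", "v")),
    class = "spectral_ensemble")
  list(ar_pair = ar_pair, toy_layout = toy_layout, spectral_toy = spectral_toy)
}
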