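#' Default pipeline configuration
#'
#' Single nested document binding the five pipeline stages (filter ->
#' reduce -> stochastic resonance -> score -> classify) plus the synthetic
#' generator and evaluation settings. All field-standard constants (the
#' 3-40 Hz band, `[a, b, beta, h] = [0.1, 1, 0.35, 0.1]`, K = 40 neighbours,
#' the 1.25/0.25 filter-bank weights, the 3-20 Hz and 1-40 Hz grids) live
#' here as defaults, never hard-coded in the stage logic.
#'
#' @param ... named overrides, nested lists merged over the defaults
#'   (e.g. `filter = list(order = 6)`). Unknown keys are rejected.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    filter = list(low_hz = 3, high_hz = 40, order = 4L, zero_phase = TRUE),
    reducer = list(method = "cca", reference_channel = "Oz", K = 40L,
                   subsample = 2000L, cca_scope = "per_frequency"),
    ussr = list(a = 0.1, b = 1, beta = 0.35, h = 0.1, D = 0, x0 = 0, v0 = 0,
                input_scale = 1, guard = 1e3, seed = 1L),
    scorer = list(method = "cca", use_harmonic = TRUE),
    fbcca = list(n_subbands = 5L, weight_a = 1.25, weight_b = 0.25),
    grid = list(stimulus_low_hz = 3, stimulus_high_hz = 20,
                spectrum_low_hz = 1, spectrum_high_hz = 40,
                step_hz = 0.5, harmonics = 2L),
    synthetic = list(duration = 3, fs = 1000, n_channels = 8L,
                     amp_fundamental = 5, harmonic_ratio = 0.1,
                     noise_alpha = 1, snr_db = -16, trials_per_freq = 1L),
    evaluation = list(lengths = c(3, 2.5, 2, 1.5, 1), seed = 1L,
                      methods = c("cca", "fbcca", "cca_ussr"))
  )
  cfg <- merge_config(defaults, list(...), path = "")
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

# recursive merge rejecting keys absent from the defaults (typo safety)
merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0L) return(defaults)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == ""))
    stop("configuration overrides must be named")
  for (key in nm) {
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key '%s%s'", path, key))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], as.list(overrides[[key]]),
                                      paste0(path, key, "."))
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  # constructors perform the detailed range checks
  filter_spec(cfg$filter$low_hz, cfg$filter$high_hz, cfg$filter$order,
              cfg$filter$zero_phase)
  do.call(ussr_params, cfg$ussr)
  fbcca_params(cfg$fbcca$n_subbands, cfg$fbcca$weight_a, cfg$fbcca$weight_b)
  if (!cfg$reducer$method %in% c("car", "pca", "mds", "lle", "cca"))
    stop("reducer.method must be one of car, pca, mds, lle, cca")
  if (!cfg$reducer$cca_scope %in% c("per_frequency", "single_best"))
    stop("reducer.cca_scope must be per_frequency or single_best")
  if (!cfg$scorer$method %in% c("cca", "psda"))
    stop("scorer.method must be cca or psda")
  with(cfg$grid, {
    if (!(stimulus_low_hz < stimulus_high_hz && spectrum_low_hz < spectrum_high_hz
          && step_hz > 0 && harmonics >= 1))
      stop("invalid grid block")
  })
  invisible(cfg)
}

config_stimulus_freqs <- function(cfg)
  seq(cfg$grid$stimulus_low_hz, cfg$grid$stimulus_high_hz, by = cfg$grid$step_hz)

config_spectrum_freqs <- function(cfg)
  seq(cfg$grid$spectrum_low_hz, cfg$grid$spectrum_high_hz, by = cfg$grid$step_hz)

config_method <- function(cfg) {
  # evaluation.methods entries name scorers directly; the reducer+scorer
  # blocks define the composite method when "ussr" is requested
  paste0(cfg$reducer$method, "_ussr")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly through [yaml::read_yaml()]; unknown keys are
#' rejected on read.
#'
#' @param path YAML file path.
#' @return `read_config` returns a validated `pipeline_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param cfg a [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

decode_args <- function(cfg) {
  list(ussr = do.call(ussr_params, cfg$ussr),
       fbcca = fbcca_params(cfg$fbcca$n_subbands, cfg$fbcca$weight_a,
                            cfg$fbcca$weight_b),
       cca_scope = cfg$reducer$cca_scope,
       reference_channel = cfg$reducer$reference_channel,
       K = cfg$reducer$K, subsample = cfg$reducer$subsample)
}

#' Decode a set of epochs end-to-end
#'
#' Runs the full five-stage pipeline (filter -> reduce -> stochastic
#' resonance -> score -> classify) on every epoch and writes a prediction
#' table, per-epoch score spectra (optional) and a provenance log.
#'
#' @param cfg a [pipeline_config()] or path to its YAML file.
#' @param input list of [eeg_epoch()] objects, or a directory of epoch CSVs
#'   written by [write_epoch_csv()].
#' @param out_dir optional output directory for `predictions.csv`,
#'   `spectrum_<i>.csv` and `provenance.json`.
#' @param method method name (default: composite from the config's reducer).
#' @param write_spectra also write one spectrum CSV per epoch.
#' @return data.frame with columns `epoch`, `true_freq`, `prediction`,
#'   `correct`, `tie`, invisibly carrying the spectra as an attribute.
#' @export
run_decode <- function(cfg, input, out_dir = NULL, method = NULL,
                       write_spectra = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  epochs <- load_epochs(input)
  if (is.null(method)) method <- config_method(cfg)
  fspec <- filter_spec(cfg$filter$low_hz, cfg$filter$high_hz,
                       cfg$filter$order, cfg$filter$zero_phase)
  stim <- config_stimulus_freqs(cfg)
  args <- decode_args(cfg)
  n <- n_samples(epochs[[1]])
  bank <- make_template_bank(stim, k = cfg$grid$harmonics,
                             fs = epochs[[1]]$fs, n_samples = n)
  preds <- vector("list", length(epochs))
  spectra <- vector("list", length(epochs))
  for (i in seq_along(epochs)) {
    fe <- bandpass(epochs[[i]], fspec)
    res <- decode_epoch(fe, method, bank, stim, ussr = args$ussr,
                        fbcca = args$fbcca, scorer = cfg$scorer$method,
                        cca_scope = args$cca_scope,
                        reference_channel = args$reference_channel,
                        K = args$K, subsample = args$subsample)
    spectra[[i]] <- res$spectrum
    preds[[i]] <- data.frame(
      epoch = i, true_freq = epochs[[i]]$true_freq,
      prediction = as.numeric(res$prediction),
      correct = abs(as.numeric(res$prediction) - epochs[[i]]$true_freq) < .freq_tol,
      tie = isTRUE(attr(res$prediction, "tie")))
  }
  tab <- do.call(rbind, preds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, "predictions.csv"), row.names = FALSE)
    if (write_spectra)
      for (i in seq_along(spectra))
        write.csv(as.data.frame(spectra[[i]]),
                  file.path(out_dir, sprintf("spectrum_%03d.csv", i)),
                  row.names = FALSE)
    log_provenance(cfg, out_dir, method = method, n_epochs = length(epochs))
  }
  attr(tab, "spectra") <- spectra
  tab
}

#' Benchmark configured methods across data lengths
#'
#' Generates a labelled synthetic dataset from the config's `synthetic` block
#' (or uses supplied epochs), evaluates every configured method at every
#' configured data length, and writes a benchmark-table-style CSV plus a JSON
#' summary.
#'
#' @param cfg a [pipeline_config()] or YAML path.
#' @param out_dir optional output directory (`benchmark.csv`,
#'   `benchmark_summary.json`, `provenance.json`).
#' @param epochs optional list of labelled epochs; default generates one
#'   synthetic trial set per the config.
#' @return The `evaluation_report` data.frame.
#' @export
run_benchmark <- function(cfg, out_dir = NULL, epochs = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  stim <- config_stimulus_freqs(cfg)
  if (is.null(epochs)) {
    sb <- cfg$synthetic
    base <- synthetic_config(f_target = stim[1], duration = sb$duration,
                             fs = sb$fs, n_channels = sb$n_channels,
                             amp_fundamental = sb$amp_fundamental,
                             harmonic_ratio = sb$harmonic_ratio,
                             noise_alpha = sb$noise_alpha, snr_db = sb$snr_db)
    epochs <- generate_dataset(stim, sb$trials_per_freq, base,
                               seed = cfg$evaluation$seed)
  }
  args <- decode_args(cfg)
  fspec <- filter_spec(cfg$filter$low_hz, cfg$filter$high_hz,
                       cfg$filter$order, cfg$filter$zero_phase)
  report <- data_length_sweep(
    epochs, lengths = cfg$evaluation$lengths,
    methods = cfg$evaluation$methods, stimulus_freqs = stim,
    filter = fspec, k = cfg$grid$harmonics, ussr = args$ussr,
    fbcca = args$fbcca, scorer = cfg$scorer$method,
    cca_scope = args$cca_scope,
    reference_channel = args$reference_channel,
    K = args$K, subsample = args$subsample)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(report), file.path(out_dir, "benchmark.csv"),
              row.names = FALSE)
    summ <- lapply(split(as.data.frame(report), report$method), function(d)
      list(mean_accuracy_pct = mean(d$accuracy_pct),
           sd_accuracy_pct = if (nrow(d) > 1) sd(d$accuracy_pct) else 0,
           mean_itr_bits_per_min = mean(d$itr_bits_per_min),
           sd_itr_bits_per_min = if (nrow(d) > 1) sd(d$itr_bits_per_min) else 0))
    jsonlite::write_json(summ, file.path(out_dir, "benchmark_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_provenance(cfg, out_dir, methods = cfg$evaluation$methods,
                   n_epochs = length(epochs))
  }
  report
}

#' Write the canonical synthetic fixture sets
#'
#' Materializes the datasets the test-suite properties are built on: a
#' noiseless 35-class sweep, an SNR ladder, and a signal-free (noise-only)
#' null set, each as long-format epoch CSVs plus a manifest listing every
#' file with its generation parameters.
#'
#' @param seed master seed.
#' @param out_dir writable output directory.
#' @param duration trial length in seconds.
#' @param snr_ladder_db SNR levels of the ladder set.
#' @param n_null number of noise-only epochs.
#' @return Path of the manifest JSON, invisibly.
#' @export
make_fixtures <- function(seed = 1L, out_dir, duration = 3,
                          snr_ladder_db = c(-6, -14, -22), n_null = 5L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  stim <- stimulus_grid()
  add <- function(epoch, name, params) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    write_epoch_csv(epoch, path)
    manifest[[length(manifest) + 1L]] <<- c(list(file = basename(path)), params)
  }
  base <- synthetic_config(f_target = stim[1], duration = duration,
                           snr_db = Inf, seed = seed)
  sweep <- generate_dataset(stim, 1L, base, seed = seed)
  for (i in seq_along(sweep))
    add(sweep[[i]], sprintf("noiseless_f%04.1f", stim[i]),
        list(set = "noiseless_sweep", f_target = stim[i], snr_db = "Inf",
             duration = duration, seed = seed))
  for (s in snr_ladder_db) {
    cfg <- synthetic_config(f_target = 10, duration = duration, snr_db = s,
                            seed = seed + round(100 * abs(s)))
    add(generate_epoch(cfg), sprintf("ladder_snr%+03.0f", s),
        list(set = "snr_ladder", f_target = 10, snr_db = s,
             duration = duration, seed = cfg$seed))
  }
  for (i in seq_len(n_null)) {
    # signal 60 dB below background: effectively noise-only, unlabelled
    cfg <- synthetic_config(f_target = 10, duration = duration,
                            snr_db = -60, seed = seed + 10000L + i)
    e <- generate_epoch(cfg)
    e$true_freq <- NA_real_
    add(e, sprintf("null_%02d", i),
        list(set = "null_noise", snr_db = -60, duration = duration,
             seed = cfg$seed))
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

load_epochs <- function(input) {
  if (is.list(input) && all(vapply(input, inherits, logical(1), "eeg_epoch")))
    return(input)
  if (inherits(input, "eeg_epoch")) return(list(input))
  if (is.character(input) && length(input) == 1L && dir.exists(input)) {
    files <- sort(list.files(input, pattern = "\\.csv$", full.names = TRUE))
    files <- files[!grepl("manifest", files)]
    if (length(files) == 0L) stop(sprintf("no epoch CSVs found in '%s'", input))
    return(lapply(files, read_epoch_csv))
  }
  stop("`input` must be epochs or a directory of epoch CSVs")
}

log_provenance <- function(cfg, out_dir, ...) {
  info <- list(config = unclass(cfg), ...,
               package_version = as.character(utils::packageVersion("ssvepsr")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(info, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}
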