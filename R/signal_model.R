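#' Construct a single-trial multichannel EEG epoch
#'
#' An `eeg_epoch` holds one stimulation trial as a channels-by-samples matrix
#' in microvolts together with its sampling rate and, for labelled data, the
#' true stimulus frequency used for evaluation.
#'
#' @param data numeric matrix, `n_channels x n_samples`, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of channel labels, one per row of
#'   `data`. Defaults to the standard 8-channel occipital montage
#'   POz, PO3, PO4, PO5, PO6, Oz, O1, O2 when `data` has 8 rows.
#' @param true_freq optional true stimulus frequency in Hz (`NA` if unknown).
#' @return An object of class `eeg_epoch`: a list with elements `data`, `fs`,
#'   `channel_names`, `true_freq`.
#' @export
eeg_epoch <- function(data, fs, channel_names = NULL, true_freq = NA_real_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L || ncol(data) < 2L)
    stop("`data` must be a numeric matrix with >= 1 channel and >= 2 samples")
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channel_names)) {
    channel_names <- if (nrow(data) == 8L) default_channels()
                     else paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data))
    stop("`channel_names` must have one label per channel")
  structure(
    list(data = data, fs = fs,
         channel_names = as.character(channel_names),
         true_freq = as.numeric(true_freq)),
    class = "eeg_epoch")
}

default_channels <- function() c("POz", "PO3", "PO4", "PO5", "PO6", "Oz", "O1", "O2")

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz (%.3g s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (is.finite(x$true_freq)) sprintf(", true_freq = %g Hz", x$true_freq) else ""))
  invisible(x)
}

n_samples <- function(epoch) ncol(epoch$data)

#' Truncate an epoch to its first `duration` seconds
#'
#' Keeps the earliest (stimulus-onset-aligned) samples, as in online BCI use.
#'
#' @param epoch an [eeg_epoch()].
#' @param duration length to keep, in seconds.
#' @return A shortened `eeg_epoch`.
#' @export
truncate_epoch <- function(epoch, duration) {
  n <- round(duration * epoch$fs)
  if (n < 2L || n > n_samples(epoch))
    stop("`duration` must keep between 2 samples and the full epoch")
  eeg_epoch(epoch$data[, seq_len(n), drop = FALSE], epoch$fs,
            epoch$channel_names, epoch$true_freq)
}

#' Build sine/cosine reference templates for a set of candidate frequencies
#'
#' For each candidate frequency f the template is the `2k x n_samples` matrix
#' with rows cos(2*pi*j*f*t), sin(2*pi*j*f*t) for harmonics j = 1..k, on the
#' time axis t = 1/fs, 2/fs, ..., n_samples/fs. These are the reference
#' signals correlated against the EEG (or against a stochastic-resonance
#' trajectory) by the CCA-type scorers.
#'
#' @param freqs candidate frequencies in Hz (ascending, unique).
#' @param k number of harmonics per template (default 2: fundamental plus
#'   first harmonic, which suits the low-harmonic motion-checkerboard regime).
#' @param fs sampling rate in Hz.
#' @param n_samples number of samples per template.
#' @return An object of class `template_bank`: list with `freqs`, `k`, `fs`,
#'   `n_samples`, and `templates` (one matrix per frequency, in order).
#' @export
make_template_bank <- function(freqs, k = 2L, fs, n_samples) {
  freqs <- as.numeric(freqs)
  if (length(freqs) == 0L) stop("`freqs` must be non-empty")
  if (is.unsorted(freqs, strictly = TRUE)) stop("`freqs` must be ascending and unique")
  if (n_samples < 2L) stop("`n_samples` must be >= 2")
  if (max(freqs) * k >= fs / 2)
    stop(sprintf("harmonic %g Hz at or above Nyquist (%g Hz)", max(freqs) * k, fs / 2))
  t <- seq_len(n_samples) / fs
  templates <- lapply(freqs, function(f) {
    rows <- lapply(seq_len(k), function(j)
      rbind(cos(2 * pi * j * f * t), sin(2 * pi * j * f * t)))
    do.call(rbind, rows)
  })
  structure(list(freqs = freqs, k = as.integer(k), fs = fs,
                 n_samples = as.integer(n_samples), templates = templates),
            class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %d frequencies (%g-%g Hz), k = %d, %d samples @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$k, x$n_samples, x$fs))
  invisible(x)
}

#' Look up the template matrix for one candidate frequency
#'
#' @param bank a [make_template_bank()] object.
#' @param f frequency in Hz; must match a bank frequency.
#' @return The `2k x n_samples` template matrix.
#' @export
get_template <- function(bank, f) {
  i <- which(abs(bank$freqs - f) < .freq_tol)
  if (length(i) != 1L) stop(sprintf("frequency %g Hz not in template bank", f))
  bank$templates[[i]]
}

#' The stimulus frequency grid of the emulated recording setup
#'
#' 35 target frequencies from 3 to 20 Hz at 0.5 Hz spacing.
#' @return Numeric vector of length 35.
#' @export
stimulus_grid <- function() seq(3, 20, by = 0.5)

#' The dense frequency grid used for coefficient spectra
#'
#' 1 to 40 Hz at 0.5 Hz spacing (79 points).
#' @return Numeric vector of length 79.
#' @export
spectrum_grid <- function() seq(1, 40, by = 0.5)

#' Configuration for the synthetic SSVEP generator
#'
#' Describes one simulated trial: a sinusoidal steady-state response at the
#' gazed frequency (with a weak first harmonic, as elicited by ring-shaped
#' motion-checkerboard stimuli) projected onto the channels through a gain
#' vector, plus 1/f^alpha colored background noise with a white-noise floor,
#' scaled to a per-channel signal-to-background power ratio.
#'
#' @param f_target stimulus frequency in Hz.
#' @param duration trial length in seconds (default 3, the stimulation window).
#' @param fs sampling rate in Hz (default 1000).
#' @param n_channels number of channels (default 8, occipital montage).
#' @param amp_fundamental amplitude of the fundamental in microvolts.
#' @param harmonic_ratio amplitude of the 2f component relative to the
#'   fundamental (default 0.1: almost no harmonic content).
#' @param phase fundamental phase in radians, or `NA` to draw it uniformly
#'   from the seeded stream (the harmonic phase is drawn likewise).
#' @param mixing per-channel gain vector in `[0, 1]`, or `NULL` for all-ones
#'   with seeded +/-20 percent jitter (unknown scalp projection stand-in).
#' @param noise_alpha exponent of the 1/f^alpha background (default 1).
#' @param snr_db per-channel SSVEP-to-background power ratio in dB; `Inf`
#'   yields a noiseless epoch.
#' @param seed integer seed; identical config and seed give identical output.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(f_target, duration = 3, fs = 1000, n_channels = 8L,
                             amp_fundamental = 5, harmonic_ratio = 0.1,
                             phase = NA_real_, mixing = NULL, noise_alpha = 1,
                             snr_db = -16, seed = 1L) {
  if (f_target <= 0 || f_target >= fs / 2) stop("`f_target` must lie in (0, fs/2)")
  if (2 * f_target >= fs / 2 && harmonic_ratio > 0)
    stop("harmonic 2*f_target at or above Nyquist")
  if (harmonic_ratio < 0) stop("`harmonic_ratio` must be >= 0")
  if (!is.null(mixing)) {
    if (length(mixing) != n_channels) stop("`mixing` must have `n_channels` entries")
    if (any(mixing < 0 | mixing > 1)) stop("`mixing` entries must lie in [0, 1]")
  }
  if (round(duration * fs) < 2) stop("`duration` too short")
  structure(list(f_target = f_target, duration = duration, fs = fs,
                 n_channels = as.integer(n_channels),
                 amp_fundamental = amp_fundamental,
                 harmonic_ratio = harmonic_ratio, phase = phase,
                 mixing = mixing, noise_alpha = noise_alpha,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "synthetic_config")
}

# 1/f^alpha colored noise via spectral shaping of white Gaussian noise,
# unit-variance, plus a white floor at `white_frac` of the colored power
colored_noise <- function(n, alpha, white_frac = 0.1) {
  w <- rnorm(n)
  if (alpha == 0) {
    col <- w
  } else {
    W <- fft(w)
    k <- seq_len(n) - 1L
    f <- pmin(k, n - k) / n      # two-sided frequency magnitude
    shape <- c(0, f[-1]^(-alpha / 2))
    col <- Re(fft(W * shape, inverse = TRUE)) / n
    col <- col / sd(col)
  }
  noise <- col + sqrt(white_frac) * rnorm(n)
  noise / sd(noise)
}

#' Generate one synthetic SSVEP epoch
#'
#' Each channel is `mixing[c] * A * (sin(2*pi*f*t + phi) +
#' harmonic_ratio * sin(4*pi*f*t + phi2))` plus background noise (1/f^alpha
#' colored plus a white floor) scaled so that the empirical per-channel
#' SSVEP-to-background power ratio equals `snr_db` exactly.
#'
#' @param cfg a [synthetic_config()].
#' @return An [eeg_epoch()] with `true_freq = cfg$f_target`.
#' @export
generate_epoch <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$duration * cfg$fs)
    t <- seq_len(n) / cfg$fs
    phi <- if (is.na(cfg$phase)) runif(1, 0, 2 * pi) else cfg$phase
    phi2 <- if (is.na(cfg$phase)) runif(1, 0, 2 * pi) else cfg$phase
    mixing <- if (is.null(cfg$mixing)) {
      pmin(pmax(1 - runif(cfg$n_channels, -0.2, 0.2), 0), 1)
    } else cfg$mixing
    wave <- cfg$amp_fundamental *
      (sin(2 * pi * cfg$f_target * t + phi) +
       cfg$harmonic_ratio * sin(4 * pi * cfg$f_target * t + phi2))
    data <- matrix(0, cfg$n_channels, n)
    lin_snr <- 10^(cfg$snr_db / 10)
    for (c in seq_len(cfg$n_channels)) {
      sig <- mixing[c] * wave
      if (is.infinite(cfg$snr_db) && cfg$snr_db > 0) {
        data[c, ] <- sig
        next
      }
      noise <- colored_noise(n, cfg$noise_alpha)
      pn <- mean(noise^2)
      if (pn <= 0) stop("zero background power with finite `snr_db` requested")
      scale <- sqrt(mean(sig^2) / (pn * lin_snr))
      if (!is.finite(scale)) stop("`snr_db` produces non-finite noise scaling")
      data[c, ] <- sig + scale * noise
    }
    eeg_epoch(data, cfg$fs, true_freq = cfg$f_target)
  })
}

#' Generate a labelled dataset of synthetic epochs
#'
#' Produces `length(freqs) * trials_per_freq` epochs; each epoch's seed is
#' derived deterministically from the master seed, so identical calls give
#' identical datasets.
#'
#' @param freqs stimulus frequencies in Hz.
#' @param trials_per_freq trials per frequency (>= 1).
#' @param cfg_base a [synthetic_config()] supplying all other parameters
#'   (its `f_target` and `seed` are overridden per epoch).
#' @param seed master integer seed.
#' @return A list of [eeg_epoch()] objects, frequency-major order.
#' @export
generate_dataset <- function(freqs, trials_per_freq, cfg_base, seed = 1L) {
  stopifnot(inherits(cfg_base, "synthetic_config"))
  if (trials_per_freq < 1L) stop("`trials_per_freq` must be >= 1")
  epochs <- vector("list", length(freqs) * trials_per_freq)
  idx <- 1L
  for (f in freqs) {
    for (r in seq_len(trials_per_freq)) {
      cfg <- cfg_base
      cfg$f_target <- f
      cfg$seed <- (as.integer(seed) + 7919L * idx) %% 2147483647L
      epochs[[idx]] <- generate_epoch(cfg)
      idx <- idx + 1L
    }
  }
  epochs
}

#' Write / read an epoch as long-format CSV
#'
#' Plain-text interchange format: columns `channel`, `sample_index`, `value`,
#' with sampling rate and label carried in commented header lines.
#'
#' @param epoch an [eeg_epoch()].
#' @param path CSV file path.
#' @return `write_epoch_csv` returns `path` invisibly; `read_epoch_csv`
#'   returns an [eeg_epoch()].
#' @export
write_epoch_csv <- function(epoch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", epoch$fs), con)
  writeLines(sprintf("# true_freq=%.10g", epoch$true_freq), con)
  df <- data.frame(
    channel = rep(epoch$channel_names, each = ncol(epoch$data)),
    sample_index = rep(seq_len(ncol(epoch$data)), nrow(epoch$data)),
    value = as.vector(t(epoch$data)))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epoch_csv
#' @param path CSV file path.
#' @export
read_epoch_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  fs <- as.numeric(sub("# fs=", "", hdr[1], fixed = TRUE))
  tf <- as.numeric(sub("# true_freq=", "", hdr[2], fixed = TRUE))
  df <- read.csv(path, comment.char = "#")
  chans <- unique(df$channel)
  n <- max(df$sample_index)
  data <- matrix(NA_real_, length(chans), n)
  for (i in seq_along(chans)) {
    sub <- df[df$channel == chans[i], ]
    data[i, sub$sample_index] <- sub$value
  }
  eeg_epoch(data, fs, chans, tf)
}
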