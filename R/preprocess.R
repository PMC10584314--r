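#' Band-pass filter specification
#'
#' Defaults follow standard SSVEP preprocessing: a 3-40 Hz Butterworth
#' passband, order 4, applied forward-backward (zero phase) so spectral peaks
#' stay aligned with the reference templates.
#'
#' @param low_hz lower passband edge in Hz.
#' @param high_hz upper passband edge in Hz.
#' @param order Butterworth design order (per edge; >= 1).
#' @param zero_phase apply forward-backward (`TRUE`, default) or single-pass.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 3, high_hz = 40, order = 4L, zero_phase = TRUE) {
  if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (order < 1L) stop("`order` must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# odd (point-symmetric) reflection padding, scipy-style
reflect_pad <- function(x, p) {
  n <- length(x)
  c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
}

#' Band-pass filter an EEG epoch
#'
#' Applies a Butterworth band-pass channel-wise. In zero-phase mode the signal
#' is reflect-padded by one filter startup length, filtered forward and
#' backward, and trimmed, so in-band components keep their phase (no group
#' delay) at the cost of squaring the magnitude response.
#'
#' @param epoch an [eeg_epoch()].
#' @param spec a [filter_spec()].
#' @return A filtered [eeg_epoch()] of identical shape; the `true_freq` label
#'   is preserved.
#' @export
bandpass <- function(epoch, spec = filter_spec()) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(spec, "filter_spec"))
  if (spec$high_hz >= epoch$fs / 2)
    stop("`high_hz` must be below Nyquist for this epoch")
  n <- n_samples(epoch)
  pad <- min(n - 1L, ceiling(3 * epoch$fs / spec$low_hz))
  if (n <= 2L * spec$order + 2L)
    stop("epoch too short for stable filtering")
  bf <- signal::butter(spec$order,
                       c(spec$low_hz, spec$high_hz) / (epoch$fs / 2),
                       type = "pass")
  out <- epoch$data
  for (c in seq_len(nrow(out))) {
    x <- reflect_pad(out[c, ], pad)
    y <- signal::filter(bf, x)
    if (spec$zero_phase) y <- rev(signal::filter(bf, rev(y)))
    out[c, ] <- y[(pad + 1L):(pad + n)]
  }
  if (!all(is.finite(out))) stop("filter produced non-finite output (unstable design)")
  eeg_epoch(out, epoch$fs, epoch$channel_names, epoch$true_freq)
}
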