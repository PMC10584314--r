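#' Information transfer rate (bits per minute)
#'
#' Wolpaw ITR for an M-class selection with accuracy `sigma` and decision
#' time `T` seconds:
#' `ITR = (60/T) * (log2 M + sigma log2 sigma + (1-sigma) log2((1-sigma)/(M-1)))`.
#' The endpoints use the `0 * log2(0) = 0` limit, so the value is finite on
#' the whole interval and exactly zero at chance level `sigma = 1/M`.
#'
#' @param sigma mean recognition accuracy in `[0, 1]` (vectorized).
#' @param M number of gaze frequencies (>= 2).
#' @param T data length in seconds (> 0).
#' @return ITR in bits/min.
#' @export
compute_itr <- function(sigma, M = 35L, T = 2) {
  if (any(sigma < 0 | sigma > 1)) stop("`sigma` must lie in [0, 1]")
  if (any(M < 2L)) stop("`M` must be >= 2")
  if (any(T <= 0)) stop("`T` must be positive")
  xlx <- function(p) ifelse(p <= 0, 0, p * log2(p))
  bits <- log2(M) + xlx(sigma) + ifelse(sigma >= 1, 0,
                                        (1 - sigma) * log2((1 - sigma) / (M - 1)))
  (60 / T) * bits
}

#' Recognition accuracy in percent
#'
#' @param predictions predicted frequencies (Hz).
#' @param truths true stimulus frequencies (Hz), same length.
#' @return `100 * matches / n`.
#' @export
accuracy <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) == 0L)
    stop("`predictions` and `truths` must be non-empty and equal length")
  100 * mean(abs(as.numeric(predictions) - as.numeric(truths)) < .freq_tol)
}

#' Coefficient spectrum over the dense 1-40 Hz grid
#'
#' Correlation (or power) between the processed signal and the reference
#' templates at 0.5 Hz intervals from 1 to 40 Hz (79 points), using the
#' configured method — the diagnostic curve on which target and interference
#' peaks are read off.
#'
#' @param epoch a band-pass filtered [eeg_epoch()].
#' @param method method name as in [decode_epoch()].
#' @param grid candidate grid (default [spectrum_grid()]).
#' @param k harmonics per template.
#' @param ... options passed through to the scorer.
#' @return A [score_spectrum()] over the grid.
#' @export
coefficient_spectrum <- function(epoch, method = "cca_ussr",
                                 grid = spectrum_grid(), k = 2L, ...) {
  bank <- make_template_bank(grid, k = k, fs = epoch$fs,
                             n_samples = n_samples(epoch))
  decode_epoch(epoch, method, bank, stimulus_freqs = grid, ...)$spectrum
}

#' Paired comparison of two per-unit accuracy vectors
#'
#' Two-sided paired t-test on matched accuracy (or correctness) samples.
#' Identical vectors are the documented degenerate case: `t = 0`, `p = 1`.
#' A non-zero constant difference (zero variance) is signalled as an error.
#'
#' @param acc_a,acc_b paired numeric vectors (n >= 2).
#' @return List with `statistic`, `df`, `p_value`, `mean_diff`.
#' @export
paired_comparison <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2L)
    stop("need paired samples with n >= 2")
  d <- acc_a - acc_b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, df = length(d) - 1L, p_value = 1, mean_diff = 0))
    stop("zero-variance non-zero differences: t statistic undefined")
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Evaluate decoding methods on a labelled dataset
#'
#' Filters each epoch, runs each method, and reports accuracy and the
#' matching ITR. This is the engine behind [run_benchmark()] and
#' [data_length_sweep()].
#'
#' @param epochs list of labelled [eeg_epoch()] objects.
#' @param methods character vector of method names (see [decode_epoch()]).
#' @param stimulus_freqs classification targets (also `M` for the ITR).
#' @param filter a [filter_spec()] applied before scoring.
#' @param k harmonics per template.
#' @param ussr a [ussr_params()].
#' @param fbcca an [fbcca_params()].
#' @param ... further options for [decode_epoch()].
#' @return An `evaluation_report`: data.frame with columns `method`,
#'   `data_length_s`, `n_trials`, `accuracy_pct`, `itr_bits_per_min`,
#'   `n_ties`; per-trial predictions in `attr(, "predictions")`.
#' @export
evaluate_dataset <- function(epochs, methods, stimulus_freqs = stimulus_grid(),
                             filter = filter_spec(), k = 2L,
                             ussr = ussr_params(), fbcca = fbcca_params(), ...) {
  stopifnot(length(epochs) > 0L)
  filtered <- lapply(epochs, bandpass, spec = filter)
  n <- n_samples(filtered[[1]])
  fs <- filtered[[1]]$fs
  bank <- make_template_bank(stimulus_freqs, k = k, fs = fs, n_samples = n)
  truths <- vapply(epochs, function(e) e$true_freq, numeric(1))
  rows <- list(); preds_all <- list()
  for (m in methods) {
    preds <- numeric(length(filtered)); ties <- 0L
    for (i in seq_along(filtered)) {
      pr <- decode_epoch(filtered[[i]], m, bank, stimulus_freqs,
                         ussr = ussr, fbcca = fbcca, ...)$prediction
      ties <- ties + as.integer(isTRUE(attr(pr, "tie")))
      preds[i] <- as.numeric(pr)
    }
    acc <- accuracy(preds, truths)
    rows[[m]] <- data.frame(
      method = m, data_length_s = n / fs, n_trials = length(filtered),
      accuracy_pct = acc,
      itr_bits_per_min = compute_itr(acc / 100, M = length(stimulus_freqs),
                                     T = n / fs),
      n_ties = ties)
    preds_all[[m]] <- data.frame(trial = seq_along(preds), method = m,
                                 truth = truths, prediction = preds,
                                 correct = abs(preds - truths) < .freq_tol)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "predictions") <- do.call(rbind, preds_all)
  class(report) <- c("evaluation_report", "data.frame")
  report
}

#' Accuracy and ITR across data lengths
#'
#' Truncates every epoch to its first `T` seconds (stimulus-onset aligned,
#' as in online use), re-runs classification, and reports accuracy and ITR
#' per method and length.
#'
#' @param epochs list of labelled [eeg_epoch()] objects.
#' @param lengths data lengths in seconds (default 3, 2.5, 2, 1.5, 1).
#' @param methods method names.
#' @param ... passed to [evaluate_dataset()].
#' @return An `evaluation_report` with one row per (method, length).
#' @export
data_length_sweep <- function(epochs, lengths = c(3, 2.5, 2, 1.5, 1),
                              methods = "cca", ...) {
  dur <- min(vapply(epochs, function(e) n_samples(e) / e$fs, numeric(1)))
  if (any(lengths > dur + .freq_tol))
    stop("requested length exceeds epoch duration")
  out <- lapply(lengths, function(T) {
    evaluate_dataset(lapply(epochs, truncate_epoch, duration = T),
                     methods = methods, ...)
  })
  report <- do.call(rbind, lapply(out, function(r) { attr(r, "predictions") <- NULL; r }))
  rownames(report) <- NULL
  attr(report, "predictions") <- do.call(rbind, lapply(out, attr, "predictions"))
  class(report) <- c("evaluation_report", "data.frame")
  report
}
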