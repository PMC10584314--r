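#' Per-candidate-frequency discriminant scores
#'
#' @param freqs candidate frequencies (ascending, unique).
#' @param scores finite numeric scores, one per candidate.
#' @param method label of the scorer that produced them.
#' @return An object of class `score_spectrum`.
#' @export
score_spectrum <- function(freqs, scores, method) {
  if (length(freqs) != length(scores)) stop("freqs and scores lengths differ")
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be ascending and unique")
  if (!all(is.finite(scores))) stop("scores contain non-finite values")
  structure(list(freqs = as.numeric(freqs), scores = as.numeric(scores),
                 method = method),
            class = "score_spectrum")
}

#' @export
print.score_spectrum <- function(x, ...) {
  i <- which.max(x$scores)
  cat(sprintf("<score_spectrum> %s over %d candidates; peak %.4g at %g Hz\n",
              x$method, length(x$freqs), x$scores[i], x$freqs[i]))
  invisible(x)
}

#' @export
as.data.frame.score_spectrum <- function(x, ...) {
  data.frame(freq_hz = x$freqs, score = x$scores)
}

#' Filter-bank CCA parameters
#'
#' Sub-band weighting `w_i = i^(-weight_a) + weight_b` with the usual
#' constants 1.25 and 0.25. Default sub-bands follow the harmonic-progressive
#' design scaled to the 3-20 Hz stimulus range: band i spans `[3 i, 40]` Hz.
#'
#' @param n_subbands number of sub-bands N (>= 1).
#' @param weight_a,weight_b weight constants (positive).
#' @param subband_edges optional list of `c(low_hz, high_hz)` pairs
#'   overriding the default design.
#' @return An object of class `fbcca_params`.
#' @export
fbcca_params <- function(n_subbands = 5L, weight_a = 1.25, weight_b = 0.25,
                         subband_edges = NULL) {
  if (n_subbands < 1L) stop("`n_subbands` must be >= 1")
  if (weight_a <= 0 || weight_b <= 0) stop("weight constants must be positive")
  if (is.null(subband_edges))
    subband_edges <- lapply(seq_len(n_subbands), function(i) c(3 * i, 40))
  if (length(subband_edges) != n_subbands)
    stop("`subband_edges` must have one pair per sub-band")
  for (e in subband_edges)
    if (length(e) != 2L || e[1] <= 0 || e[1] >= e[2]) stop("invalid sub-band edges")
  structure(list(n_subbands = as.integer(n_subbands), weight_a = weight_a,
                 weight_b = weight_b, subband_edges = subband_edges),
            class = "fbcca_params")
}

#' Sub-band weight of the filter-bank combination
#'
#' `w_i = i^(-weight_a) + weight_b`, strictly decreasing in the band index.
#'
#' @param i sub-band index in `1..n_subbands`.
#' @param p an [fbcca_params()].
#' @return The weight (vectorized over `i`).
#' @export
fbcca_weight <- function(i, p = fbcca_params()) {
  if (any(i < 1L | i > p$n_subbands)) stop("sub-band index out of range")
  i^(-p$weight_a) + p$weight_b
}

#' Classic CCA frequency scoring
#'
#' Scores each candidate by the first canonical correlation between the
#' (already filtered) epoch and that candidate's reference template; the
#' maximizing candidate is the recognized gaze frequency.
#'
#' @param epoch an [eeg_epoch()] (band-pass filtered).
#' @param bank a [make_template_bank()] matching the epoch length.
#' @return A [score_spectrum()] with method `"cca"`.
#' @export
cca_score <- function(epoch, bank) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(bank, "template_bank"))
  if (bank$n_samples != n_samples(epoch))
    stop("template bank length does not match epoch")
  scores <- vapply(bank$templates,
                   function(Y) cca_fit(epoch$data, Y)$rho, numeric(1))
  score_spectrum(bank$freqs, scores, "cca")
}

#' Filter-bank CCA frequency scoring
#'
#' Band-pass filters the epoch into N sub-bands, computes the canonical
#' correlation `rho_i` per sub-band and candidate, and combines them as
#' `sum_i w_i * rho_i^2`.
#'
#' @param epoch an [eeg_epoch()].
#' @param bank a [make_template_bank()].
#' @param p an [fbcca_params()].
#' @param filter_order Butterworth order for the sub-band filters.
#' @return A [score_spectrum()] with method `"fbcca"`.
#' @export
fbcca_score <- function(epoch, bank, p = fbcca_params(), filter_order = 4L) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(p, "fbcca_params"))
  scores <- numeric(length(bank$freqs))
  for (i in seq_len(p$n_subbands)) {
    e <- p$subband_edges[[i]]
    if (e[2] >= epoch$fs / 2) stop("sub-band edge at or above Nyquist")
    sub <- bandpass(epoch, filter_spec(e[1], e[2], order = filter_order))
    rho <- vapply(bank$templates,
                  function(Y) cca_fit(sub$data, Y)$rho, numeric(1))
    scores <- scores + fbcca_weight(i, p) * rho^2
  }
  score_spectrum(bank$freqs, scores, "fbcca")
}

#' Power-spectral frequency scoring of a 1-D signal
#'
#' Evaluates the discrete-time Fourier amplitude exactly at each candidate
#' frequency (single-frequency evaluation, not snapped to FFT bins, since the
#' 0.5 Hz grid does not align with bins at 1-3 s lengths) and scores by
#' unnormalized amplitude squared, plus the 2f term when `use_harmonic`.
#'
#' @param values numeric vector or [reduced_signal()].
#' @param fs sampling rate in Hz.
#' @param freqs candidate frequencies.
#' @param use_harmonic add the first-harmonic power (default `TRUE`).
#' @return A [score_spectrum()] with method `"psda"`.
#' @export
psda_score <- function(values, fs, freqs, use_harmonic = TRUE) {
  if (inherits(values, "reduced_signal")) { fs <- values$fs; values <- values$values }
  values <- as.numeric(values)
  fmax <- if (use_harmonic) 2 * max(freqs) else max(freqs)
  if (fmax >= fs / 2) stop("candidate (or harmonic) frequency at or above Nyquist")
  n <- length(values)
  idx <- seq_len(n)
  amp2 <- function(f) Mod(sum(values * exp(-2i * pi * f * idx / fs)))^2
  scores <- vapply(freqs, function(f) {
    amp2(f) + if (use_harmonic) amp2(2 * f) else 0
  }, numeric(1))
  score_spectrum(freqs, scores, "psda")
}

#' Composite reduce -> stochastic resonance -> score pipeline
#'
#' For the CAR/PCA/MDS/LLE reducers the epoch is reduced once, passed through
#' the bistable filter once, and the mean-removed trajectory is scored at
#' every candidate. For the CCA reducer with `cca_scope = "per_frequency"`
#' (default) the projection, filtering and scoring are re-run per candidate
#' frequency — each candidate is scored on the trajectory of its own
#' projection, which is what produces the coefficient spectrum. With
#' `cca_scope = "single_best"` the projection of the plain-CCA-best candidate
#' is reused for all candidates.
#'
#' Scoring a 1-D trajectory with `"cca"` uses [cca_fit()] with the one-row
#' signal against the template: the maximal correlation between the
#' trajectory and the best linear combination of template rows.
#'
#' @param epoch an [eeg_epoch()] (band-pass filtered).
#' @param bank a [make_template_bank()].
#' @param reducer one of `"car"`, `"pca"`, `"mds"`, `"lle"`, `"cca"`.
#' @param p a [ussr_params()].
#' @param scorer `"cca"` or `"psda"`.
#' @param cca_scope `"per_frequency"` or `"single_best"` (CCA reducer only).
#' @param reference_channel,K,subsample reducer options (see [reduce_epoch()]).
#' @param use_harmonic for the PSDA scorer.
#' @return A [score_spectrum()] with method `"<reducer>_ussr"`.
#' @export
ussr_pipeline_score <- function(epoch, bank, reducer = "cca",
                                p = ussr_params(), scorer = c("cca", "psda"),
                                cca_scope = c("per_frequency", "single_best"),
                                reference_channel = "Oz", K = 40L,
                                subsample = 2000L, use_harmonic = TRUE) {
  scorer <- match.arg(scorer)
  cca_scope <- match.arg(cca_scope)
  reducer <- match.arg(reducer, c("car", "pca", "mds", "lle", "cca"))
  stopifnot(inherits(bank, "template_bank"))
  score_traj <- function(x, f) {
    if (scorer == "cca") {
      if (sd(x) == 0) return(0)
      cca_fit(rbind(x), get_template(bank, f))$rho
    } else {
      psda_score(x, epoch$fs, f, use_harmonic)$scores
    }
  }
  filt <- function(sig) {
    traj <- ussr_filter(sig, p)
    traj$x - mean(traj$x)
  }
  if (reducer == "cca" && cca_scope == "per_frequency") {
    scores <- vapply(bank$freqs, function(f) {
      score_traj(filt(cca_reduce(epoch, bank, f)), f)
    }, numeric(1))
  } else {
    red <- if (reducer == "cca") {
      best <- bank$freqs[which.max(cca_score(epoch, bank)$scores)]
      cca_reduce(epoch, bank, best)
    } else {
      reduce_epoch(epoch, reducer, reference_channel = reference_channel,
                   K = K, subsample = subsample)
    }
    x <- filt(red)
    scores <- vapply(bank$freqs, function(f) score_traj(x, f), numeric(1))
  }
  score_spectrum(bank$freqs, scores, paste0(reducer, "_ussr"))
}

#' Pick the gazed stimulus frequency from a score spectrum
#'
#' Restricts the spectrum to the stimulus frequencies (even when it covers a
#' denser grid) and returns the one with maximal score; exact ties are broken
#' by the lowest frequency and flagged via the `"tie"` attribute.
#'
#' @param spectrum a [score_spectrum()].
#' @param stimulus_freqs stimulus frequencies (must all be in the spectrum).
#' @return Predicted frequency in Hz, with attribute `tie` (logical).
#' @export
classify <- function(spectrum, stimulus_freqs = stimulus_grid()) {
  stopifnot(inherits(spectrum, "score_spectrum"))
  if (length(stimulus_freqs) == 0L) stop("empty candidate set")
  idx <- vapply(stimulus_freqs, function(f) {
    i <- which(abs(spectrum$freqs - f) < .freq_tol)
    if (length(i) != 1L) stop(sprintf("stimulus frequency %g Hz not in spectrum", f))
    i
  }, integer(1))
  s <- spectrum$scores[idx]
  winners <- which(s == max(s))
  pred <- stimulus_freqs[min(winners)]
  attr(pred, "tie") <- length(winners) > 1L
  pred
}

#' Decode one epoch with a named method
#'
#' Convenience dispatcher binding the preprocessing already done upstream to
#' the scorers: `"cca"`, `"fbcca"`, `"psda"` (on the reference channel), or
#' `"<reducer>_ussr"` composites.
#'
#' @param epoch a filtered [eeg_epoch()].
#' @param method method name.
#' @param bank template bank over the candidate grid.
#' @param stimulus_freqs classification targets.
#' @param ussr a [ussr_params()].
#' @param fbcca an [fbcca_params()].
#' @param ... further options passed to [ussr_pipeline_score()].
#' @return List with `prediction` (Hz) and `spectrum` (a [score_spectrum()]).
#' @export
decode_epoch <- function(epoch, method, bank,
                         stimulus_freqs = stimulus_grid(),
                         ussr = ussr_params(), fbcca = fbcca_params(), ...) {
  spec <- switch(method,
    cca   = cca_score(epoch, bank),
    fbcca = fbcca_score(epoch, bank, fbcca),
    psda  = {
      i <- match("Oz", epoch$channel_names)
      if (is.na(i)) i <- 1L
      psda_score(epoch$data[i, ], epoch$fs, bank$freqs)
    },
    cca_ussr = ussr_pipeline_score(epoch, bank, "cca", ussr, ...),
    car_ussr = ussr_pipeline_score(epoch, bank, "car", ussr, ...),
    pca_ussr = ussr_pipeline_score(epoch, bank, "pca", ussr, ...),
    mds_ussr = ussr_pipeline_score(epoch, bank, "mds", ussr, ...),
    lle_ussr = ussr_pipeline_score(epoch, bank, "lle", ussr, ...),
    stop(sprintf("unknown method '%s'", method)))
  list(prediction = classify(spec, stimulus_freqs), spectrum = spec)
}
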