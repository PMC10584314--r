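test_that("filter-bank weights follow i^(-a) + b and decrease", {
  p <- fbcca_params()
  expect_equal(fbcca_weight(1, p), 1.25)
  expect_equal(fbcca_weight(2, p), 2^(-1.25) + 0.25, tolerance = 1e-12)
  expect_equal(fbcca_weight(2, p), 0.670448, tolerance = 1e-6)
  w <- fbcca_weight(1:5, p)
  expect_true(all(diff(w) < 0))
  expect_error(fbcca_weight(6, p), "out of range")
})

test_that("cca_score peaks at the true frequency of a rank-1 epoch", {
  # weak 2f content (as SSVEP has) breaks the exact tie with the f/2
  # candidate, whose k = 2 template contains f as its harmonic row
  ep <- rank1_epoch(10, harmonic_ratio = 0.1)
  bank <- make_template_bank(stimulus_grid(), 2, 1000, 2000)
  sp <- cca_score(ep, bank)
  expect_equal(sp$freqs[which.max(sp$scores)], 10)
  expect_gt(max(sp$scores), 0.999)
  # a zero-harmonic sinusoid scores ~1 at the target too
  sp0 <- cca_score(rank1_epoch(10), bank)
  expect_gt(sp0$scores[sp0$freqs == 10], 0.999)
  expect_true(all(sp$scores >= 0 & sp$scores <= 1))
  # incommensurate candidates stay low on this integer-period window
  far <- sp$scores[abs(sp$freqs - 10) > 2 & abs(sp$freqs - 20) > 1 &
                     abs(sp$freqs - 5) > 1]
  expect_true(all(far <= 0.1))
})

test_that("single-band FBCCA ranks candidates like plain CCA", {
  ep <- generate_epoch(synthetic_config(f_target = 9, snr_db = 0, seed = 81))
  ep <- bandpass(truncate_epoch(ep, 1))
  bank <- make_template_bank(seq(6, 12, 0.5), 2, 1000, 1000)
  p1 <- fbcca_params(n_subbands = 1, subband_edges = list(c(3, 40)))
  s1 <- fbcca_score(ep, bank, p1)
  s0 <- cca_score(bandpass(ep), bank)
  expect_equal(order(s1$scores), order(s0$scores))
  expect_true(all(s1$scores >= 0))
})

test_that("FBCCA finds the target of a high-SNR epoch", {
  ep <- generate_epoch(synthetic_config(f_target = 9, snr_db = 20, seed = 82))
  ep <- bandpass(truncate_epoch(ep, 2))
  bank <- make_template_bank(stimulus_grid(), 2, 1000, 2000)
  sp <- fbcca_score(ep, bank)
  expect_equal(sp$freqs[which.max(sp$scores)], 9)
})

test_that("psda_score matches the closed-form projection on integer periods", {
  fs <- 1000; n <- 2000
  x <- sin(2 * pi * 10 * seq_len(n) / fs)
  sp <- psda_score(x, fs, c(8, 10, 12.5), use_harmonic = FALSE)
  expect_equal(sp$freqs[which.max(sp$scores)], 10)
  expect_equal(sp$scores[2], (n / 2)^2, tolerance = 1e-6)
  # brute-force sin/cos correlation oracle
  t <- seq_len(n) / fs
  oracle <- sum(x * sin(2*pi*10*t))^2 + sum(x * cos(2*pi*10*t))^2
  expect_equal(sp$scores[2], oracle, tolerance = 1e-9)
  expect_error(psda_score(x, fs, 600), "Nyquist")
})

test_that("white noise alone produces no dominant candidate", {
  set.seed(83)
  x <- rnorm(2000)
  sp <- psda_score(x, 1000, stimulus_grid())
  expect_lt(max(sp$scores), 5 * median(sp$scores))
})

test_that("the composite reduce-USSR-score pipeline recognizes the target", {
  ep <- generate_epoch(synthetic_config(f_target = 11.5, snr_db = 30, seed = 84))
  ep <- bandpass(truncate_epoch(ep, 2))
  bank <- make_template_bank(stimulus_grid(), 2, 1000, 2000)
  sp <- ussr_pipeline_score(ep, bank, reducer = "cca")
  expect_equal(sp$freqs[which.max(sp$scores)], 11.5)
  expect_equal(sp$method, "cca_ussr")
  # PSDA scoring route
  sp2 <- ussr_pipeline_score(ep, bank, reducer = "pca", scorer = "psda")
  expect_equal(sp2$freqs[which.max(sp2$scores)], 11.5)
})

test_that("spectra over the dense grid have 79 points", {
  ep <- rank1_epoch(10, duration = 1)
  bank <- make_template_bank(spectrum_grid(), 2, 1000, 1000)
  sp <- ussr_pipeline_score(ep, bank, reducer = "pca")
  expect_length(sp$scores, 79)
})

test_that("a flat-line reference channel degrades gracefully", {
  set.seed(85)
  data <- matrix(rnorm(8 * 1000), 8, 1000)
  data[6, ] <- 0   # Oz dead
  ep <- eeg_epoch(data, 1000)
  bank <- make_template_bank(seq(8, 12, 0.5), 2, 1000, 1000)
  sp <- ussr_pipeline_score(ep, bank, reducer = "car")
  expect_true(all(is.finite(sp$scores)))
})

test_that("classification restricts to stimulus frequencies and breaks ties low", {
  freqs <- seq(1, 40, 0.5)
  scores <- rep(0, length(freqs))
  scores[freqs == 7] <- 1
  expect_equal(as.numeric(classify(score_spectrum(freqs, scores, "cca"))), 7)
  scores[freqs == 9] <- 1
  pred <- classify(score_spectrum(freqs, scores, "cca"))
  expect_equal(as.numeric(pred), 7)
  expect_true(attr(pred, "tie"))
  # huge out-of-stimulus score is ignored
  scores2 <- rep(0.1, length(freqs))
  scores2[freqs == 33] <- 5
  scores2[freqs == 12] <- 0.2
  pred2 <- classify(score_spectrum(freqs, scores2, "cca"))
  expect_equal(as.numeric(pred2), 12)
  expect_error(classify(score_spectrum(freqs, scores2, "cca"), numeric(0)),
               "empty candidate")
  expect_error(classify(score_spectrum(c(8, 9), c(1, 2), "cca"), c(8, 9.5)),
               "not in spectrum")
})

test_that("scorer rankings are invariant to positive rescaling of the epoch", {
  ep <- generate_epoch(synthetic_config(f_target = 8, snr_db = 0, seed = 86))
  ep <- bandpass(truncate_epoch(ep, 1))
  ep2 <- eeg_epoch(37.5 * ep$data, ep$fs, ep$channel_names, ep$true_freq)
  bank <- make_template_bank(seq(6, 12, 0.5), 2, 1000, 1000)
  expect_equal(order(cca_score(ep, bank)$scores),
               order(cca_score(ep2, bank)$scores))
  expect_equal(order(fbcca_score(ep, bank)$scores),
               order(fbcca_score(ep2, bank)$scores))
  i <- match("Oz", ep$channel_names)
  expect_equal(order(psda_score(ep$data[i, ], 1000, seq(6, 12, 0.5))$scores),
               order(psda_score(ep2$data[i, ], 1000, seq(6, 12, 0.5))$scores))
})

test_that("all four scorers decode noiseless epochs at spot-checked frequencies", {
  bank <- make_template_bank(stimulus_grid(), 2, 1000, 1000)
  for (f in c(3, 11.5, 20)) {
    ep <- generate_epoch(synthetic_config(f_target = f, duration = 1,
                                          snr_db = Inf, seed = 87))
    fe <- bandpass(ep)
    for (m in c("cca", "fbcca", "psda", "cca_ussr"))
      expect_equal(as.numeric(decode_epoch(fe, m, bank)$prediction), f,
                   info = sprintf("%s at %g Hz", m, f))
  }
})
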