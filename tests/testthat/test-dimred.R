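test_that("CAR subtracts the channel mean from the reference electrode", {
  ep <- eeg_epoch(matrix(5, 8, 100), 1000)
  expect_equal(car_reduce(ep, "Oz")$values, rep(0, 100))
  ep2 <- eeg_epoch(matrix(1:8, 8, 100), 1000)
  expect_equal(car_reduce(ep2, "PO6")$values, rep(5 - 4.5, 100))
  expect_error(car_reduce(ep2, "Cz"), "unknown channel")
})

test_that("CAR retains the reference channel's spectral line", {
  set.seed(9)
  n <- 2000; fs <- 1000
  data <- matrix(rnorm(8 * n), 8, n)
  data[6, ] <- sin(2 * pi * 10 * seq_len(n) / fs)   # Oz
  ep <- eeg_epoch(data, fs)
  vals <- car_reduce(ep, "Oz")$values
  a10 <- line_amp(vals, 10, fs)
  bg <- median(sapply(c(6.3, 8.1, 13.7, 17.2), line_amp, x = vals, fs = fs))
  expect_gt(a10, 10 * bg)
})

test_that("PCA recovers a rank-1 signal exactly", {
  n <- 500
  s <- sin(2 * pi * 7 * seq_len(n) / 1000) + 0.3 * rnorm(n)
  ep <- eeg_epoch(outer(c(1, 0.5, -0.8, 0.2), s), 1000)
  r <- pca_reduce(ep)
  expect_equal(abs(cor(r$values, s)), 1, tolerance = 1e-9)
  expect_gt(r$meta$explained_var, 0.999)
  expect_equal(mean(r$values), 0, tolerance = 1e-10)
})

test_that("PCA on isotropic noise explains ~1/8 and maximizes variance", {
  set.seed(21)
  ep <- eeg_epoch(matrix(rnorm(8 * 4000), 8, 4000), 1000)
  r <- pca_reduce(ep)
  # top sample eigenvalue of an isotropic 8-dim covariance at n = 4000 sits
  # ~1 + 2*sqrt(8/4000) above 1, so allow that sampling bias
  expect_equal(r$meta$explained_var, 1 / 8, tolerance = 0.1)
  # brute-force: no random unit direction beats the PC1 variance
  set.seed(22)
  Xc <- scale(t(ep$data), center = TRUE, scale = FALSE)
  rand_vars <- replicate(1000, {
    w <- rnorm(8); w <- w / sqrt(sum(w^2))
    var(as.vector(Xc %*% w))
  })
  expect_gte(var(r$values), max(rand_vars))
})

test_that("PCA direction matches a power-iteration oracle", {
  set.seed(23)
  A <- matrix(rnorm(8 * 3), 8, 3) %*% matrix(rnorm(3 * 600), 3, 600) +
    0.1 * matrix(rnorm(8 * 600), 8, 600)
  ep <- eeg_epoch(A, 1000)
  r <- pca_reduce(ep)
  C <- stats::cov(t(A))
  v <- power_iteration(C)
  expect_equal(abs(sum(v * r$meta$loading)), 1, tolerance = 1e-6)
})

test_that("MDS embedding is exact for collinear points and duplicates", {
  dir <- c(1, 2, -1) / sqrt(6)
  coef <- c(0, 1, 3, 3, -2, 5)
  pts <- outer(coef, dir)                      # collinear in channel space
  ep <- eeg_epoch(t(pts), 1000)
  y <- mds_reduce(ep)$values
  expect_equal(as.matrix(dist(y)), as.matrix(dist(pts)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(y[3], y[4], tolerance = 1e-12)  # duplicated sample points
})

test_that("MDS first coordinate matches a cmdscale oracle on rank-2 data", {
  set.seed(31)
  n <- 200
  pts <- cbind(rnorm(n), rnorm(n)) %*% matrix(rnorm(2 * 8), 2, 8)
  ep <- eeg_epoch(t(pts), 1000)
  y <- mds_reduce(ep)$values
  oracle <- stats::cmdscale(dist(pts), k = 1)[, 1]
  expect_equal(abs(cor(y, oracle)), 1, tolerance = 1e-9)
  expect_equal(max(abs(abs(y) - abs(oracle))), 0, tolerance = 1e-6)
})

test_that("LLE weights sum to one and the embedding is standardized", {
  set.seed(41)
  ep <- eeg_epoch(matrix(rnorm(4 * 300), 4, 300), 1000)
  r <- lle_reduce(ep, K = 10)
  y <- r$values
  expect_equal(mean(y), 0, tolerance = 1e-6)
  expect_equal(mean(y^2), 1, tolerance = 1e-6)   # population unit variance
  expect_length(y, 300)
})

test_that("LLE unrolls a noiseless 1-D curve in 8-D", {
  set.seed(42)
  n <- 500
  tau <- sort(runif(n))
  curve <- cbind(sin(2 * tau), cos(3 * tau), tau, tau^2,
                 sin(5 * tau), tau^3, cos(tau), 2 * tau)
  ep <- eeg_epoch(t(curve), 1000)
  y <- lle_reduce(ep, K = 12)$values
  expect_gte(abs(cor(y, tau, method = "spearman")), 0.99)
})

test_that("cca_fit is exact when X lies in the template span", {
  n <- 2000; fs <- 1000
  t <- seq_len(n) / fs
  X <- rbind(sin(2 * pi * 10 * t))
  bank <- make_template_bank(c(10, 25), k = 1, fs = fs, n_samples = n)
  fit <- cca_fit(X, get_template(bank, 10))
  expect_equal(fit$rho, 1, tolerance = 1e-6)
  # incommensurate sinusoid over integer periods: near-zero correlation
  fit25 <- cca_fit(X, get_template(bank, 25))
  expect_lte(fit25$rho, 0.05)
})

test_that("cca_fit matches brute-force correlation maximization", {
  set.seed(51)
  for (rep in 1:3) {
    X <- matrix(rnorm(4 * 400), 4, 400)
    Y <- matrix(rnorm(2 * 400), 2, 400)
    fit <- cca_fit(X, Y)
    expect_equal(fit$rho, cca_brute(X, Y, n_starts = 40, seed = rep),
                 tolerance = 1e-4)
    cc <- stats::cancor(t(X), t(Y))
    expect_equal(fit$rho, cc$cor[1], tolerance = 1e-6)
    # fitted projections have unit variance and correlate at rho
    px <- as.vector(crossprod(fit$wx, X - rowMeans(X)))
    py <- as.vector(crossprod(fit$wy, Y - rowMeans(Y)))
    expect_equal(var(px), 1, tolerance = 1e-8)
    expect_equal(var(py), 1, tolerance = 1e-8)
    expect_equal(cor(px, py), fit$rho, tolerance = 1e-6)  # ridge offset
  }
})

test_that("cca_fit rho is invariant to invertible channel re-mixing", {
  set.seed(52)
  X <- matrix(rnorm(4 * 500), 4, 500)
  Y <- matrix(rnorm(2 * 500), 2, 500)
  M <- matrix(rnorm(16), 4, 4) + 4 * diag(4)
  expect_equal(cca_fit(M %*% X, Y)$rho, cca_fit(X, Y)$rho, tolerance = 1e-6)
})

test_that("reducers ignore a common offset added to every channel", {
  set.seed(53)
  ep <- eeg_epoch(matrix(rnorm(4 * 300), 4, 300), 1000)
  shifted <- eeg_epoch(ep$data + 100, 1000, ep$channel_names)
  expect_equal(pca_reduce(shifted)$values, pca_reduce(ep)$values, tolerance = 1e-9)
  expect_equal(mds_reduce(shifted)$values, mds_reduce(ep)$values, tolerance = 1e-9)
  expect_equal(lle_reduce(shifted, K = 8)$values, lle_reduce(ep, K = 8)$values,
               tolerance = 1e-6)
})

test_that("cca_reduce projects onto the fitted channel weights", {
  ep <- rank1_epoch(10)
  bank <- make_template_bank(c(7, 10, 13), k = 2, fs = 1000, n_samples = 2000)
  r <- cca_reduce(ep, bank, 10)
  expect_length(r$values, 2000)
  t <- seq_len(2000) / 1000
  expect_gte(abs(cor(r$values, sin(2 * pi * 10 * t))), 0.999)
  expect_equal(r$meta$f, 10)
  expect_error(cca_reduce(ep, bank, 11), "not in template bank")
})

test_that("matched-frequency CCA reduction sharpens the target line", {
  ep <- generate_epoch(synthetic_config(f_target = 7, snr_db = 5, seed = 61))
  ep <- truncate_epoch(ep, 2)
  bank <- make_template_bank(c(7, 13), k = 2, fs = 1000, n_samples = 2000)
  r7 <- cca_reduce(ep, bank, 7)
  r13 <- cca_reduce(ep, bank, 13)
  expect_gt(line_amp(r7$values / sd(r7$values), 7, 1000),
            line_amp(r13$values / sd(r13$values), 7, 1000))
})
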