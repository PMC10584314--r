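# Independent oracles and small fixture builders shared across tests.

# plain-R classical RK4 for the bistable system; independent of the compiled
# integrator. `substeps` refines the step while keeping the drive's
# zero-order-hold segments aligned with input samples.
rk4_reference <- function(u, a = 0.1, b = 1, beta = 0.35, h = 0.1,
                          x0 = 0, v0 = 0, substeps = 1L) {
  n <- length(u)
  hs <- h / substeps
  x <- numeric(n)
  v <- numeric(n)
  xx <- x0; vv <- v0
  acc <- function(x, v, u) a * x - b * x^3 - beta * v + u
  for (i in seq_len(n)) {
    for (s in seq_len(substeps)) {
      k1x <- vv;              k1v <- acc(xx, vv, u[i])
      k2x <- vv + hs/2 * k1v; k2v <- acc(xx + hs/2 * k1x, vv + hs/2 * k1v, u[i])
      k3x <- vv + hs/2 * k2v; k3v <- acc(xx + hs/2 * k2x, vv + hs/2 * k2v, u[i])
      k4x <- vv + hs * k3v;   k4v <- acc(xx + hs * k3x, vv + hs * k3v, u[i])
      xx <- xx + hs/6 * (k1x + 2*k2x + 2*k3x + k4x)
      vv <- vv + hs/6 * (k1v + 2*k2v + 2*k3v + k4v)
    }
    x[i] <- xx; v[i] <- vv
  }
  list(x = x, v = v)
}

# rank-1 epoch: gain vector times a pure sinusoid (plus optional harmonic)
rank1_epoch <- function(f, fs = 1000, duration = 2, n_channels = 8,
                        gains = NULL, phase = 0, harmonic_ratio = 0) {
  n <- round(duration * fs)
  t <- seq_len(n) / fs
  s <- sin(2 * pi * f * t + phase) +
    harmonic_ratio * sin(4 * pi * f * t + phase)
  if (is.null(gains)) gains <- seq(0.8, 1.2, length.out = n_channels)
  eeg_epoch(outer(gains, s), fs, true_freq = f)
}

# unnormalized amplitude at frequency f (t = 1/fs convention)
line_amp <- function(x, f, fs) {
  n <- length(x)
  Mod(sum(x * exp(-2i * pi * f * seq_len(n) / fs)))
}

# brute-force first canonical correlation: direct maximization of
# cor(wx'X, wy'Y) over unit vectors from many seeded random starts
cca_brute <- function(X, Y, n_starts = 60, seed = 1) {
  Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
  obj <- function(par) {
    wx <- par[seq_len(nrow(X))]
    wy <- par[-seq_len(nrow(X))]
    if (sum(wx^2) == 0 || sum(wy^2) == 0) return(0)
    -abs(cor(as.vector(crossprod(wx, Xc)), as.vector(crossprod(wy, Yc))))
  }
  best <- 0
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    p0 <- rnorm(nrow(X) + nrow(Y))
    o <- optim(p0, obj, method = "BFGS", control = list(maxit = 500))
    best <- max(best, -o$value)
  }
  best
}

# dominant covariance eigenvector by power iteration
power_iteration <- function(C, iters = 500) {
  v <- rep(1, nrow(C)) / sqrt(nrow(C))
  for (i in seq_len(iters)) {
    v <- C %*% v
    v <- v / sqrt(sum(v^2))
  }
  as.vector(v)
}
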