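#' One-dimensional reduction of a multichannel epoch
#'
#' Container returned by all reducers: the 1-D signal handed to the
#' stochastic-resonance filter, plus enough metadata to reproduce the
#' projection.
#'
#' @param values numeric vector, length `n_samples`.
#' @param method one of `"car"`, `"pca"`, `"mds"`, `"lle"`, `"cca"`.
#' @param fs sampling rate in Hz.
#' @param meta named list of method-specific parameters actually used.
#' @return An object of class `reduced_signal`.
#' @export
reduced_signal <- function(values, method, fs, meta = list()) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("reduced signal contains non-finite values")
  structure(list(values = values, method = method, fs = fs, meta = meta),
            class = "reduced_signal")
}

#' @export
print.reduced_signal <- function(x, ...) {
  cat(sprintf("<reduced_signal> %s, %d samples @ %g Hz\n",
              toupper(x$method), length(x$values), x$fs))
  invisible(x)
}

# sign convention for direction vectors with arbitrary sign: make the
# largest-magnitude coefficient positive
fix_sign <- function(w) if (w[which.max(abs(w))] < 0) -w else w

#' Common-average-reference reduction
#'
#' Subtracts the per-sample mean of all channels from the chosen reference
#' electrode: `values = V_reference - mean over channels`.
#'
#' @param epoch an [eeg_epoch()].
#' @param reference_channel channel label (default `"Oz"`, the occipital
#'   electrode that retains the strongest SSVEP).
#' @return A [reduced_signal()] with method `"car"`.
#' @export
car_reduce <- function(epoch, reference_channel = "Oz") {
  stopifnot(inherits(epoch, "eeg_epoch"))
  i <- match(reference_channel, epoch$channel_names)
  if (is.na(i)) stop(sprintf("unknown channel label '%s'", reference_channel))
  vals <- epoch$data[i, ] - colMeans(epoch$data)
  reduced_signal(vals, "car", epoch$fs,
                 list(reference_channel = reference_channel))
}

#' First-principal-component reduction
#'
#' Treats channels as variables and samples as observations; returns the
#' mean-centred score series of the first principal component (the direction
#' of maximal variance).
#'
#' @param epoch an [eeg_epoch()].
#' @return A [reduced_signal()] with method `"pca"`; `meta` stores the loading
#'   vector and the explained-variance fraction.
#' @export
pca_reduce <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (n_samples(epoch) <= nrow(epoch$data))
    stop("need more samples than channels")
  if (all(apply(epoch$data, 1, var) == 0)) stop("degenerate zero-variance epoch")
  p <- prcomp(t(epoch$data), center = TRUE, scale. = FALSE)
  a1 <- fix_sign(p$rotation[, 1])
  scores <- as.vector(scale(t(epoch$data), center = TRUE, scale = FALSE) %*% a1)
  reduced_signal(scores, "pca", epoch$fs,
                 list(loading = a1,
                      explained_var = p$sdev[1]^2 / sum(p$sdev^2)))
}

#' Classical multidimensional-scaling reduction
#'
#' Each time sample is a point in channel space; classical MDS on their
#' Euclidean distances returns the first principal coordinate. Because the
#' double-centred Gram matrix of Euclidean distances shares its spectrum with
#' the small channels-by-channels scatter matrix, the coordinate is computed
#' from that `p x p` eigendecomposition without materializing the
#' `n x n` matrix.
#'
#' @param epoch an [eeg_epoch()].
#' @param subsample optional cap on the number of points used to estimate the
#'   principal axis (all points are then projected onto it); `Inf` (default)
#'   uses every sample — the scatter-matrix route is O(n) so no cap is needed.
#' @return A [reduced_signal()] with method `"mds"`.
#' @export
mds_reduce <- function(epoch, subsample = Inf) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (nrow(epoch$data) < 2L) stop("MDS needs >= 2 channels")
  pts <- t(epoch$data)
  pts <- sweep(pts, 2, colMeans(pts))
  if (!all(is.finite(pts))) stop("non-finite distances")
  est <- if (is.finite(subsample) && nrow(pts) > subsample) {
    pts[round(seq(1, nrow(pts), length.out = subsample)), , drop = FALSE]
  } else pts
  S <- crossprod(est)                      # p x p scatter: same spectrum as Gram
  v1 <- fix_sign(eigen(S, symmetric = TRUE)$vectors[, 1])
  reduced_signal(as.vector(pts %*% v1), "mds", epoch$fs, list(axis = v1))
}

#' Locally-linear-embedding reduction
#'
#' Standard LLE over time samples as points in channel space: each point is
#' reconstructed from its K nearest neighbours with weights summing to one,
#' and the 1-D embedding minimizing the reconstruction cost under zero-mean,
#' unit-variance constraints is the eigenvector of `(I-W)'(I-W)` for the
#' smallest non-zero eigenvalue.
#'
#' @param epoch an [eeg_epoch()].
#' @param K number of nearest neighbours (default 40).
#' @param subsample cap on the number of points (default 2000); beyond it the
#'   embedding is computed on an even subsample and linearly interpolated
#'   back, keeping the O(n^2) neighbour search and O(n^3) eigenproblem at
#'   desk scale.
#' @param reg local Gram regularization factor: `reg * trace` is added to the
#'   diagonal when the neighbourhood Gram matrix is (near-)singular, the
#'   standard conditioning fix when K exceeds the intrinsic dimension.
#' @return A [reduced_signal()] with method `"lle"`; `meta` records `K`, the
#'   weight matrix row-sum check and whether regularization triggered.
#' @export
lle_reduce <- function(epoch, K = 40L, subsample = 2000L, reg = 1e-3) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  pts_all <- t(epoch$data)
  n_all <- nrow(pts_all)
  if (K >= n_all) stop("`K` must be smaller than the number of samples")
  idx <- if (n_all > subsample) round(seq(1, n_all, length.out = subsample)) else seq_len(n_all)
  pts <- pts_all[idx, , drop = FALSE]
  n <- nrow(pts)
  d2 <- as.matrix(stats::dist(pts))^2
  W <- matrix(0, n, n)
  regularized <- FALSE
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(K + 1L)]       # skip self
    Z <- sweep(pts[nb, , drop = FALSE], 2, pts[i, ])
    G <- tcrossprod(Z)
    tr <- sum(diag(G))
    if (tr <= 0) tr <- 1
    if (K > ncol(pts) || rcond(G) < 1e-10) {
      G <- G + reg * tr * diag(K)
      regularized <- TRUE
    }
    w <- solve(G, rep(1, K))
    W[i, nb] <- w / sum(w)
  }
  M <- crossprod(diag(n) - W)
  e <- eigen(M, symmetric = TRUE)
  y <- e$vectors[, n - 1L]                 # smallest non-zero eigenvalue
  y <- y - mean(y)
  y <- fix_sign(y / sqrt(mean(y^2)))       # population unit variance
  if (n < n_all) y <- approx(idx, y, xout = seq_len(n_all))$y
  reduced_signal(y, "lle", epoch$fs,
                 list(K = as.integer(K), regularized = regularized))
}

#' Canonical correlation between an EEG block and a reference template
#'
#' Finds weight vectors `wx`, `wy` maximizing the correlation between the
#' projections `wx'X` and `wy'Y`, via the generalized eigenproblem on the
#' (ridge-regularized) covariance matrices.
#'
#' @param X numeric matrix `n_channels x n_samples` (rows are variables).
#' @param Y numeric matrix `2k x n_samples` (reference template).
#' @param ridge relative ridge added to each auto-covariance diagonal
#'   (`ridge * trace`), for rank-deficient blocks.
#' @return An object of class `cca_projection`: list with `wx`, `wy`
#'   (scaled so each projection has unit variance), and `rho` in `[0, 1]`.
#'   The sign convention makes `cor(wx'X, wy'Y) >= 0` and
#'   `cor(wx'X, Y[1, ]) >= 0`.
#' @export
cca_fit <- function(X, Y, ridge = 1e-8) {
  X <- rbind(X); Y <- rbind(Y)
  n <- ncol(X)
  if (ncol(Y) != n) stop("X and Y must have the same number of samples")
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  Cxx <- tcrossprod(Xc) / (n - 1)
  Cyy <- tcrossprod(Yc) / (n - 1)
  Cxy <- tcrossprod(Xc, Yc) / (n - 1)
  rtr <- function(C) { tr <- sum(diag(C)); if (tr <= 0) 1 else tr }
  Cxx <- Cxx + ridge * rtr(Cxx) * diag(nrow(Cxx))
  Cyy <- Cyy + ridge * rtr(Cyy) * diag(nrow(Cyy))
  Rx <- chol(Cxx)
  Ry <- chol(Cyy)
  # A = Rx^{-T} Cxy Ry^{-1}; K = A A' = Cxx^{-1/2} Cxy Cyy^{-1} Cyx Cxx^{-1/2}
  # is symmetric with eigenvalues rho^2
  B <- backsolve(Rx, Cxy, transpose = TRUE)
  A <- t(backsolve(Ry, t(B), transpose = TRUE))
  K <- tcrossprod(A)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  rho <- sqrt(min(max(e$values[1], 0), 1))
  wx <- backsolve(Rx, e$vectors[, 1])
  wy <- solve(Cyy, crossprod(Cxy, wx))
  px <- as.vector(crossprod(wx, Xc))
  py <- as.vector(crossprod(wy, Yc))
  if (sd(px) > 0) { wx <- wx / sd(px); px <- px / sd(px) }
  if (sd(py) > 0) { wy <- wy / sd(py); py <- py / sd(py) }
  safe_cor <- function(u, v) if (sd(u) == 0 || sd(v) == 0) 0 else cor(u, v)
  if (safe_cor(px, py) < 0) { wy <- -wy; py <- -py }
  if (safe_cor(px, Y[1, ]) < 0) { wx <- -wx; wy <- -wy }
  structure(list(wx = as.vector(wx), wy = as.vector(wy), rho = rho),
            class = "cca_projection")
}

#' @export
print.cca_projection <- function(x, ...) {
  cat(sprintf("<cca_projection> rho = %.4f (%d x %d weights)\n",
              x$rho, length(x$wx), length(x$wy)))
  invisible(x)
}

#' CCA spatial-filter reduction at one candidate frequency
#'
#' Projects the (row-centred) epoch onto the CCA channel weights fitted
#' against the reference template of frequency `f`: `values = wx'X`.
#'
#' @param epoch an [eeg_epoch()].
#' @param bank a [make_template_bank()] matching the epoch length.
#' @param f candidate frequency in Hz (must be in the bank).
#' @return A [reduced_signal()] with method `"cca"`; `meta` stores `f`, `wx`
#'   and `rho`.
#' @export
cca_reduce <- function(epoch, bank, f) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(bank, "template_bank"))
  if (bank$n_samples != n_samples(epoch))
    stop("template bank length does not match epoch")
  Y <- get_template(bank, f)
  fit <- cca_fit(epoch$data, Y)
  Xc <- epoch$data - rowMeans(epoch$data)
  reduced_signal(as.vector(crossprod(fit$wx, Xc)), "cca", epoch$fs,
                 list(f = f, wx = fit$wx, rho = fit$rho))
}

#' Dispatch a reducer by name
#'
#' @param epoch an [eeg_epoch()].
#' @param method one of `"car"`, `"pca"`, `"mds"`, `"lle"`, `"cca"`.
#' @param bank template bank (required for `"cca"`).
#' @param f candidate frequency (required for `"cca"`).
#' @param reference_channel for `"car"`.
#' @param K,subsample for `"lle"` / `"mds"`.
#' @return A [reduced_signal()].
#' @export
reduce_epoch <- function(epoch, method, bank = NULL, f = NULL,
                         reference_channel = "Oz", K = 40L, subsample = 2000L) {
  switch(match.arg(method, c("car", "pca", "mds", "lle", "cca")),
         car = car_reduce(epoch, reference_channel),
         pca = pca_reduce(epoch),
         mds = mds_reduce(epoch),
         lle = lle_reduce(epoch, K = K, subsample = subsample),
         cca = cca_reduce(epoch, bank, f))
}
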