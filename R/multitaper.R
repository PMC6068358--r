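# cache for DPSS tapers keyed by (n, nw, k); the tridiagonal eigenproblem is
# the expensive step and identical across epochs/sessions
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the standard symmetric tridiagonal eigenproblem
#' (Lanczos through [igraph::arpack()], dense fallback). Tapers are
#' unit-norm, mutually orthogonal, and sign-normalized so that each taper's
#' mean (or, for odd tapers, first nonzero lobe) is positive.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product; the half bandwidth is `nw / (n * dt)`.
#' @param k Number of tapers (k < 2 * nw recommended).
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 8, nw > 0, k >= 1, k < n)
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  dg <- ((n - 1 - 2 * (0:(n - 1))) / 2)^2 * cos(2 * pi * w)
  od <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  vecs <- tryCatch({
    mul <- function(x, extra = NULL) {
      y <- dg * x
      y[1:(n - 1)] <- y[1:(n - 1)] + od * x[2:n]
      y[2:n] <- y[2:n] + od * x[1:(n - 1)]
      y
    }
    ar <- igraph::arpack(mul, sym = TRUE,
                         options = list(n = n, nev = k,
                                        ncv = min(n, max(4 * k, 25)),
                                        which = "LA", maxiter = 3000))
    v <- ar$vectors
    ord <- order(ar$values, decreasing = TRUE)
    as.matrix(v)[, ord, drop = FALSE]
  }, error = function(e) {
    A <- diag(dg)
    A[cbind(1:(n - 1), 2:n)] <- od
    A[cbind(2:n, 1:(n - 1))] <- od
    eigen(A, symmetric = TRUE)$vectors[, 1:k, drop = FALSE]
  })
  for (j in seq_len(k)) {
    v <- vecs[, j]
    v <- v / sqrt(sum(v^2))
    s <- sum(v)
    if (abs(s) < 1e-8) s <- v[which(abs(v) > max(abs(v)) / 2)[1]]
    if (s < 0) v <- -v
    vecs[, j] <- v
  }
  .dpss_cache[[key]] <- vecs
  vecs
}

#' Multitaper half bandwidth
#'
#' For `k` tapers over a window of `t_s` seconds the spectral half bandwidth
#' is `(k + 1) / (2 * t_s)` Hz (equivalently `nw / t_s` with
#' `nw = (k + 1) / 2`).
#'
#' @param n_tapers Number of tapers.
#' @param t_s Window duration in seconds.
#' @return Half bandwidth in Hz.
#' @examples
#' multitaper_halfbandwidth(9, 2.25) # 2.22 Hz
#' @export
multitaper_halfbandwidth <- function(n_tapers, t_s) {
  (n_tapers + 1) / (2 * t_s)
}

#' Multitaper cross-spectral density of one epoch
#'
#' DPSS-tapered auto- and cross-spectra, averaged over tapers, assembled
#' into a Hermitian spectral density matrix on the one-sided FFT grid
#' (0..Nyquist). The time-bandwidth product defaults to
#' `(n_tapers + 1) / 2`, matching the stated half bandwidth
#' `(K + 1) / (2 T)`.
#'
#' @param epoch Samples x channels numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param n_tapers Number of DPSS tapers (default 9).
#' @param nw Time-bandwidth product; default `(n_tapers + 1) / 2`.
#' @param pad Zero-padding factor for the taper FFTs (default 2). Padding to
#'   twice the epoch length lets the implied circular grid carry the full
#'   sample autocovariance, which matters downstream: spectral factorization
#'   of an unpadded estimate hits an aliasing floor.
#' @return A [spectral_matrix()] on the `floor(pad * n / 2) + 1`-point Hz
#'   grid.
#' @export
multitaper_csd <- function(epoch, fs, n_tapers = 9, nw = NULL, pad = 2) {
  epoch <- as.matrix(epoch)
  n <- nrow(epoch)
  p <- ncol(epoch)
  if (n_tapers < 1) abort("n_tapers must be at least 1")
  nw <- nw %||% ((n_tapers + 1) / 2)
  if (n_tapers > 2 * nw) {
    abort(sprintf(
      "n_tapers = %d incompatible with time-bandwidth nw = %g (need k <= 2*nw)",
      n_tapers, nw))
  }
  tap <- dpss_tapers(n, nw, n_tapers)
  nfft <- as.integer(round(pad * n))
  nf <- nfft %/% 2L + 1L
  zpad <- matrix(0, nfft - n, p)
  Q <- array(0+0i, c(nf, p, p))
  for (kk in seq_len(n_tapers)) {
    X <- mvfft(rbind(epoch * tap[, kk], zpad))[1:nf, , drop = FALSE]
    for (i in seq_len(p)) for (j in i:p) {
      Q[, i, j] <- Q[, i, j] + X[, i] * Conj(X[, j])
    }
  }
  Q <- Q / (n_tapers * fs)
  for (i in seq_len(p)) for (j in i:p) {
    if (j > i) Q[, j, i] <- Conj(Q[, i, j])
  }
  freq <- seq(0, fs / 2, length.out = nf)
  spectral_matrix(freq, Q, fs = fs, validate = FALSE)
}

#' Average per-epoch spectral matrices
#'
#' Arithmetic mean, entry by entry and frequency by frequency, of a list of
#' spectral matrices on identical grids.
#'
#' @param qs List of [spectral_matrix()] objects.
#' @return A [spectral_matrix()].
#' @export
average_epochs <- function(qs) {
  if (length(qs) == 0) abort("cannot average an empty list of spectra")
  f0 <- qs[[1]]$freq
  for (q in qs) {
    stopifnot(inherits(q, "spectral_matrix"))
    if (length(q$freq) != length(f0) || max(abs(q$freq - f0)) > 1e-9) {
      abort("epoch spectral matrices are on different grids")
    }
  }
  acc <- qs[[1]]$Q
  if (length(qs) > 1) for (q in qs[-1]) acc <- acc + q$Q
  spectral_matrix(f0, acc / length(qs), fs = qs[[1]]$fs, validate = FALSE)
}
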