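#' Detrend and z-score one epoch
#'
#' Per channel: removes the least-squares linear trend, then subtracts the
#' mean and divides by the standard deviation across time points. A channel
#' that is constant (or exactly linear, so that the detrended series has zero
#' variance) is an error naming the channel.
#'
#' @param epoch Samples x channels numeric matrix (>= 3 samples).
#' @return Matrix of the same shape; each column has mean 0 and sd 1.
#' @export
preprocess_epoch <- function(epoch) {
  out <- detrend_epoch(epoch)
  n <- nrow(out)
  for (ch in seq_len(ncol(out))) {
    s <- sqrt(sum(out[, ch]^2) / (n - 1))
    if (s < 1e-12) {
      abort(sprintf("channel %d has zero variance after detrending", ch))
    }
    out[, ch] <- out[, ch] / s
  }
  out
}

#' @describeIn preprocess_epoch Linear detrend and mean subtraction only
#'   (no variance normalization); used for the power-summary stage.
#' @export
detrend_epoch <- function(epoch) {
  epoch <- as.matrix(epoch)
  n <- nrow(epoch)
  if (n < 3) abort("preprocessing needs at least 3 samples")
  t0 <- seq_len(n) - (n + 1) / 2            # centred time axis
  stt <- sum(t0^2)
  slope <- as.numeric(crossprod(t0, epoch)) / stt
  epoch - rep(colMeans(epoch), each = n) - outer(t0, slope)
}

#' Sliding-window sinusoid regression for line-noise removal
#'
#' In each window, least-squares fits sine and cosine terms at each line
#' frequency and subtracts the fit; the per-window estimates of the line
#' component are overlap-averaged into a full-length reconstruction which is
#' subtracted from the signal. This is a deliberately simple regression-based
#' cleaner; `n_tapers` is accepted for configuration parity with multitaper
#' pipelines but the fit itself is an untapered least squares.
#'
#' @param epoch Samples x channels numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param line_freqs Line frequencies to remove, Hz (default 50 and 150 Hz;
#'   all must lie below the Nyquist frequency).
#' @param window_s Window length in seconds (default 0.75).
#' @param step_s Step between window starts in seconds (default 0.375).
#' @param n_tapers Accepted for interface parity; unused by the regression.
#' @return Cleaned matrix of the same shape.
#' @export
remove_line_noise <- function(epoch, fs, line_freqs = c(50, 150),
                              window_s = 0.75, step_s = 0.375, n_tapers = 3) {
  epoch <- as.matrix(epoch)
  n <- nrow(epoch)
  if (any(line_freqs >= fs / 2)) {
    abort("line frequencies must lie below the Nyquist frequency")
  }
  wlen <- as.integer(round(window_s * fs))
  step <- max(1L, as.integer(round(step_s * fs)))
  if (wlen > n) abort("window is longer than the epoch")
  starts <- seq(1L, n - wlen + 1L, by = step)
  if (tail(starts, 1) + wlen - 1L < n) starts <- c(starts, n - wlen + 1L)

  est <- matrix(0, n, ncol(epoch))
  wsum <- numeric(n)
  tt <- seq_len(n) / fs
  for (s0 in starts) {
    idx <- s0:(s0 + wlen - 1L)
    X <- do.call(cbind, lapply(line_freqs, function(f) {
      cbind(cos(2 * pi * f * tt[idx]), sin(2 * pi * f * tt[idx]))
    }))
    # one QR for all channels in this window
    fit <- X %*% qr.solve(X, epoch[idx, , drop = FALSE])
    est[idx, ] <- est[idx, ] + fit
    wsum[idx] <- wsum[idx] + 1
  }
  epoch - est / wsum
}
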