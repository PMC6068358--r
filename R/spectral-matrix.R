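#' Spectral density matrix over a frequency grid
#'
#' A `spectral_matrix` stores the Hermitian cross-spectral density
#' \eqn{Q(\omega)} of a p-channel process: auto-spectra on the diagonal,
#' cross-spectra off it. Analytic spectra of AR models, common-signal
#' injection, Wilson factorization and all connectivity measures operate on
#' this container.
#'
#' @param freq Frequency grid (see [frequency_grid()]).
#' @param Q Complex array `n_freq x p x p`, Hermitian at every frequency.
#' @param fs Optional sampling rate in Hz (`NULL` for normalized grids).
#' @param validate Check Hermitian symmetry and diagonal positivity.
#' @return An object of class `spectral_matrix`.
#' @export
spectral_matrix <- function(freq, Q, fs = NULL, validate = TRUE) {
  Q <- as.array(Q)
  if (length(dim(Q)) != 3 || dim(Q)[1] != length(freq) || dim(Q)[2] != dim(Q)[3]) {
    abort("Q must be an n_freq x p x p array")
  }
  storage.mode(Q) <- "complex"
  obj <- structure(
    list(freq = as.numeric(freq), Q = Q, fs = fs %||% attr(freq, "fs"),
         p = dim(Q)[2]),
    class = "spectral_matrix"
  )
  if (validate) validate_spectral_matrix(obj)
  obj
}

validate_spectral_matrix <- function(x, tol = 1e-8) {
  Q <- x$Q
  p <- x$p
  scale <- max(abs(Q), 1e-300)
  for (i in seq_len(p)) {
    d <- Q[, i, i]
    if (max(abs(Im(d))) > tol * scale || min(Re(d)) < -tol * scale) {
      abort("auto-spectra must be real and nonnegative")
    }
    for (j in seq_len(p)) {
      if (j <= i) next
      if (max(abs(Q[, i, j] - Conj(Q[, j, i]))) > tol * scale) {
        abort("Q must be Hermitian at every frequency")
      }
    }
  }
  invisible(x)
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix> %d channels, %d frequencies (%s)\n",
              x$p, length(x$freq),
              if (is.null(x$fs)) "normalized rad" else sprintf("fs = %g Hz", x$fs)))
  invisible(x)
}

#' @describeIn spectral_matrix Long-format tibble: frequency, i, j, real, imag.
#' @param x,... Passed to methods.
#' @exportS3Method generics::tidy
tidy.spectral_matrix <- function(x, ...) {
  p <- x$p
  idx <- expand.grid(i = seq_len(p), j = seq_len(p))
  purrr::pmap_dfr(idx, function(i, j) {
    slice <- x$Q[, i, j]
    tibble::tibble(frequency = x$freq, i = i, j = j,
                   real = Re(slice), imag = Im(slice))
  }) |>
    dplyr::arrange(.data$frequency, .data$i, .data$j)
}

#' Write / read a spectral matrix as a long-format delimited table
#'
#' Columns: `frequency, i, j, real, imag` (comma separated, header row).
#'
#' @param x A `spectral_matrix`.
#' @param path Output (or input) CSV path.
#' @param fs Sampling rate to attach on read (optional).
#' @export
write_spectral_matrix <- function(x, path) {
  readr::write_csv(tidy(x), path)
  invisible(path)
}

#' @rdname write_spectral_matrix
#' @export
read_spectral_matrix <- function(path, fs = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  freq <- sort(unique(d$frequency))
  p <- max(d$i)
  Q <- array(0+0i, c(length(freq), p, p))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    dd <- d[d$i == i & d$j == j, ]
    dd <- dd[order(dd$frequency), ]
    Q[, i, j] <- complex(real = dd$real, imaginary = dd$imag)
  }
  spectral_matrix(freq, Q, fs = fs)
}

# evaluate A(w) = I - sum_l Phi(l) exp(-i w l) on a radian grid
ar_poly <- function(model, w) {
  p <- model$p
  n <- length(w)
  A <- array(0+0i, c(n, p, p))
  for (i in seq_len(p)) A[, i, i] <- 1+0i
  for (l in seq_along(model$coeffs)) {
    e <- exp(-1i * w * l)
    ph <- model$coeffs[[l]]
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (ph[i, j] != 0) A[, i, j] <- A[, i, j] - ph[i, j] * e
    }
  }
  A
}

# invert a stack of 1x1 or 2x2 complex matrices; error names the frequency
invert_stack <- function(A, freq = NULL) {
  p <- dim(A)[2]
  if (p == 1) {
    d <- A[, 1, 1]
    bad <- which(Mod(d) < 1e-300)
    if (length(bad)) {
      abort(sprintf("matrix numerically singular at frequency index %d%s",
                    bad[1],
                    if (!is.null(freq)) sprintf(" (freq %.6g)", freq[bad[1]]) else ""))
    }
    out <- A
    out[, 1, 1] <- 1 / d
    return(out)
  }
  if (p == 2) {
    det <- A[, 1, 1] * A[, 2, 2] - A[, 1, 2] * A[, 2, 1]
    bad <- which(Mod(det) < 1e-300 * pmax(Mod(A[, 1, 1] * A[, 2, 2]), 1))
    if (length(bad)) {
      abort(sprintf("matrix numerically singular at frequency index %d%s",
                    bad[1],
                    if (!is.null(freq)) sprintf(" (freq %.6g)", freq[bad[1]]) else ""))
    }
    out <- A
    out[, 1, 1] <- A[, 2, 2] / det
    out[, 2, 2] <- A[, 1, 1] / det
    out[, 1, 2] <- -A[, 1, 2] / det
    out[, 2, 1] <- -A[, 2, 1] / det
    return(out)
  }
  out <- A
  for (k in seq_len(dim(A)[1])) out[k, , ] <- solve(A[k, , ])
  out
}

# stack matrix product C(w) = A(w) B(w)
stack_mult <- function(A, B) {
  p <- dim(A)[2]
  n <- dim(A)[1]
  C <- array(0+0i, c(n, p, dim(B)[3]))
  for (i in seq_len(p)) for (j in seq_len(dim(B)[3])) {
    acc <- A[, i, 1] * B[, 1, j]
    if (p > 1) for (k in 2:p) acc <- acc + A[, i, k] * B[, k, j]
    C[, i, j] <- acc
  }
  C
}

# conjugate transpose of a stack
stack_ct <- function(A) {
  out <- Conj(A)
  aperm(out, c(1, 3, 2))
}

#' Transfer-function representation of an AR model
#'
#' Evaluates \eqn{H(\omega) = A(\omega)^{-1}} with
#' \eqn{A(\omega) = I - \sum_l \Phi(l) e^{-i\omega l}} on the supplied grid,
#' carrying the innovation covariance through unchanged.
#'
#' @param model An `ar_model` (must be stable).
#' @param freq Frequency grid (default [frequency_grid()]); Hz grids are
#'   converted using their `fs` attribute.
#' @param fs Sampling rate when `freq` is in Hz without an `fs` attribute.
#' @return An object of class `transfer_decomp` with elements `freq`, `H`
#'   (complex `n x p x p`), `noise_cov`, `fs`.
#' @examples
#' td <- ar_transfer_function(scenario_model("connected"))
#' td$H[1, 1, 1] # 1 / (1 - 0.1)
#' @export
ar_transfer_function <- function(model, freq = frequency_grid(), fs = NULL) {
  stopifnot(inherits(model, "ar_model"))
  check_stable(model)
  w <- grid_to_radians(freq, fs)
  A <- ar_poly(model, w)
  H <- invert_stack(A, freq = as.numeric(freq))
  structure(
    list(freq = as.numeric(freq), H = H, noise_cov = model$noise_cov,
         fs = fs %||% attr(freq, "fs"), p = model$p),
    class = "transfer_decomp"
  )
}

#' @export
print.transfer_decomp <- function(x, ...) {
  cat(sprintf("<transfer_decomp> %d channels, %d frequencies\n",
              x$p, length(x$freq)))
  invisible(x)
}

#' Analytic spectral density matrix of an AR model
#'
#' Computes \eqn{Q(\omega) = H(\omega)\,\Sigma\,H^*(\omega)}. With this
#' normalization the process variance equals the mean of the auto-spectrum
#' over the full frequency circle, so a unit-variance white process has
#' \eqn{Q \equiv I}.
#'
#' @inheritParams ar_transfer_function
#' @return A [spectral_matrix()].
#' @examples
#' Q <- ar_spectral_matrix(ar_model(matrix(0.1), matrix(1)))
#' Re(Q$Q[1, 1, 1]) # 1 / (1 - 0.1)^2
#' @export
ar_spectral_matrix <- function(model, freq = frequency_grid(), fs = NULL) {
  td <- ar_transfer_function(model, freq, fs)
  Q <- stack_mult(stack_mult(td$H, sigma_stack(td$noise_cov, length(td$freq))),
                  stack_ct(td$H))
  # symmetrize to kill roundoff asymmetry
  Q <- 0.5 * (Q + stack_ct(Q))
  spectral_matrix(td$freq, Q, fs = td$fs, validate = FALSE)
}

sigma_stack <- function(S, n) {
  p <- nrow(S)
  out <- array(0+0i, c(n, p, p))
  for (i in seq_len(p)) for (j in seq_len(p)) out[, i, j] <- S[i, j] + 0i
  out
}

#' The two reference simulation systems
#'
#' `scenario_model("connected")` returns the unidirectionally-connected
#' bivariate AR(1) used throughout the simulations:
#' \eqn{y_1(t) = 0.1 y_1(t-1) + \eta(t)},
#' \eqn{y_2(t) = 0.4 y_2(t-1) + 0.1 y_1(t-1) + \epsilon(t)} with unit,
#' uncorrelated noises. `scenario_model("disconnected")` returns the
#' spectral matrix of the disconnected counterpart: identical auto-spectra,
#' zero cross-spectra at every frequency.
#'
#' @param which `"connected"` or `"disconnected"`.
#' @param freq Grid used when building the disconnected spectral matrix.
#' @return An `ar_model` (connected) or a `spectral_matrix` (disconnected).
#' @export
scenario_model <- function(which = c("connected", "disconnected"),
                           freq = frequency_grid()) {
  which <- match.arg(which)
  m <- ar_model(matrix(c(0.1, 0.1, 0, 0.4), 2, 2), diag(2))
  if (which == "connected") return(m)
  Q <- ar_spectral_matrix(m, freq)
  Q$Q[, 1, 2] <- 0+0i
  Q$Q[, 2, 1] <- 0+0i
  Q
}

#' Mean neural power of a two-channel spectrum
#'
#' The flat common-signal level used in the simulation scenarios: the average
#' over the 0..Nyquist grid of the mean of the two auto-spectra,
#' \eqn{\frac{1}{2 n} \sum_\omega (S_{11}(\omega) + S_{22}(\omega))}.
#'
#' @param Q A two-channel [spectral_matrix()].
#' @return Scalar power.
#' @export
mean_neural_power <- function(Q) {
  stopifnot(inherits(Q, "spectral_matrix"), Q$p == 2)
  mean(Re(Q$Q[, 1, 1]) + Re(Q$Q[, 2, 2])) / 2
}
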