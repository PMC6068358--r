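#' Frequency grid from zero to the Nyquist frequency
#'
#' Builds the evaluation grid used by the analytic spectral functions. The
#' grid always starts at 0 and ends at the Nyquist frequency inclusive: in
#' normalized angular frequency that is \eqn{[0, \pi]} radians/sample, or
#' `[0, fs/2]` Hz when a sampling rate is supplied.
#'
#' @param n_points Number of grid points (default 512).
#' @param fs Optional sampling rate in Hz. When given, the grid is returned
#'   in Hz; otherwise in normalized radians/sample.
#' @return Numeric vector of strictly increasing frequencies with attributes
#'   `fs` (possibly `NULL`) and `unit` (`"rad"` or `"hz"`).
#' @examples
#' w <- frequency_grid(256)
#' range(w) # 0 .. pi
#' f <- frequency_grid(256, fs = 1000)
#' range(f) # 0 .. 500 Hz
#' @export
frequency_grid <- function(n_points = 512, fs = NULL) {
  stopifnot(is_scalar_number(n_points), n_points >= 2)
  if (is.null(fs)) {
    g <- seq(0, pi, length.out = n_points)
    attr(g, "unit") <- "rad"
  } else {
    stopifnot(is_scalar_number(fs), fs > 0)
    g <- seq(0, fs / 2, length.out = n_points)
    attr(g, "unit") <- "hz"
    attr(g, "fs") <- fs
  }
  g
}

# convert a grid (Hz or normalized) to normalized radians/sample
grid_to_radians <- function(freq, fs = NULL) {
  fs <- fs %||% attr(freq, "fs")
  if (is.null(fs)) return(as.numeric(freq))
  2 * pi * as.numeric(freq) / fs
}

# a grid is Wilson-compatible if it is uniform and spans 0..Nyquist
check_uniform_grid <- function(freq, fs = NULL) {
  w <- grid_to_radians(freq, fs)
  n <- length(w)
  if (n < 3) abort("frequency grid needs at least 3 points")
  if (abs(w[1]) > 1e-12 || abs(w[n] - pi) > 1e-8) {
    abort("frequency grid must span 0 to the Nyquist frequency inclusive")
  }
  dw <- diff(w)
  if (max(abs(dw - dw[1])) > 1e-8 * dw[1]) {
    abort("frequency grid must be uniformly spaced")
  }
  invisible(w)
}
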