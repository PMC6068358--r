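#' Coherence spectrum of a two-channel spectral matrix
#'
#' \eqn{C_{12}(\omega) = |S_{12}(\omega)|^2 / (S_{11}(\omega) S_{22}(\omega))},
#' clipped to \eqn{[0, 1]} within a small numerical slack.
#'
#' @param Q A two-channel [spectral_matrix()] with strictly positive
#'   auto-spectra.
#' @return Numeric vector of coherence values on `Q$freq`.
#' @examples
#' Q <- ar_spectral_matrix(scenario_model("connected"))
#' head(coherence_spectrum(Q))
#' @export
coherence_spectrum <- function(Q) {
  stopifnot(inherits(Q, "spectral_matrix"), Q$p == 2)
  s11 <- Re(Q$Q[, 1, 1]); s22 <- Re(Q$Q[, 2, 2])
  if (any(s11 <= 0) || any(s22 <= 0)) {
    abort("coherence is undefined where an auto-spectrum is zero")
  }
  C <- Mod(Q$Q[, 1, 2])^2 / (s11 * s22)
  if (any(C > 1 + 1e-12)) abort("coherence exceeded 1 beyond numerical slack")
  pmin(pmax(C, 0), 1)
}

#' Transformed coherence
#'
#' The monotone stretch \eqn{-\ln(1 - C)} linking coherence to the Granger
#' decomposition: it equals total interdependence
#' \eqn{f_{i,j} = \ln(S_{11} S_{22} / |Q|)}.
#'
#' @param C Coherence values in \eqn{[0, 1)}.
#' @param cap Behaviour at C = 1, where the transform is unbounded:
#'   `"error"` (default) or a finite numeric cap.
#' @return \eqn{-\ln(1-C)}.
#' @examples
#' transform_coherence(c(0.01, 0.99)) # 0.0101, 4.6052
#' @export
transform_coherence <- function(C, cap = "error") {
  if (any(C < 0 | C > 1, na.rm = TRUE)) abort("coherence must lie in [0, 1]")
  at_one <- !is.na(C) & C == 1
  if (any(at_one)) {
    if (identical(cap, "error")) {
      abort("transformed coherence is unbounded at C = 1")
    }
    stopifnot(is_scalar_number(cap))
  }
  out <- -log1p(-C)
  out[at_one] <- if (identical(cap, "error")) Inf else cap
  out
}

#' Granger-causality decomposition of a two-channel spectrum
#'
#' Decomposes the transformed coherence of `Q` into directional Granger
#' causalities and instantaneous interaction, using a transfer-function
#' factorization (parametric via [ar_transfer_function()] or non-parametric
#' via [wilson_factorize()]):
#' \deqn{-\ln(1 - C_{12}) = f_{1\to2} + f_{1\leftarrow2} + f_{1\cdot2}.}
#' With innovation covariance \eqn{[[\Sigma, \gamma],[\gamma, \Gamma]]} the
#' directional terms are
#' \eqn{f_{1\to2} = \ln(S_{22} / \tilde H_{22} \Gamma \tilde H_{22}^*)} and
#' \eqn{f_{1\leftarrow2} = \ln(S_{11} / \tilde H_{11} \Sigma \tilde
#' H_{11}^*)}, where the corrected transfer entries
#' \eqn{\tilde H_{22} = H_{22} + (\gamma/\Gamma) H_{21}} and
#' \eqn{\tilde H_{11} = H_{11} + (\gamma/\Sigma) H_{12}} remove the
#' instantaneous noise correlation (they reduce to \eqn{H_{22}, H_{11}} when
#' \eqn{\gamma = 0}; the corrected path is always taken). Instantaneous
#' interaction is computed directly from its closed form
#' \eqn{f_{1\cdot2} = \ln(\tilde H_{11}\Sigma\tilde H_{11}^* \cdot
#' \tilde H_{22}\Gamma\tilde H_{22}^* / |Q|)}; the decomposition-identity
#' residual is recorded as a cross-check. Instantaneous interaction can be
#' negative; it is reported, never clipped, and a `negative_instantaneous`
#' attribute flags it.
#'
#' @param Q A two-channel [spectral_matrix()].
#' @param decomp A `transfer_decomp` for `Q`; defaults to
#'   `wilson_factorize(Q)`.
#' @param cap Passed to [transform_coherence()].
#' @param max_residual Refuse factorizations whose relative residual exceeds
#'   this (default 1e-3).
#' @return A tibble of class `connectivity_spectra` with columns `frequency`,
#'   `coherence`, `transformed_coherence`, `gc_forward` (\eqn{f_{1\to2}}),
#'   `gc_backward`, `total_gc`, `instantaneous`, `pct_instantaneous` (`NA`
#'   where the transformed coherence is zero), plus attributes
#'   `decomposition_residual`, `factorization_residual` and
#'   `negative_instantaneous`.
#' @examples
#' Q <- ar_spectral_matrix(scenario_model("connected"), frequency_grid(64))
#' gd <- granger_decompose(Q)
#' gd[1, ]
#' @export
granger_decompose <- function(Q, decomp = NULL, cap = "error",
                              max_residual = 1e-3) {
  stopifnot(inherits(Q, "spectral_matrix"), Q$p == 2)
  if (is.null(decomp)) decomp <- wilson_factorize(Q)
  res <- factorization_residual(Q, decomp)
  if (res > max_residual) {
    abort(sprintf(
      "transfer decomposition does not factorize Q (relative residual %.3g > %.3g)",
      res, max_residual))
  }
  s11 <- Re(Q$Q[, 1, 1]); s22 <- Re(Q$Q[, 2, 2])
  detq <- s11 * s22 - Mod(Q$Q[, 1, 2])^2
  C <- coherence_spectrum(Q)
  fij <- transform_coherence(C, cap = cap)

  S <- decomp$noise_cov
  Sig <- S[1, 1]; Gam <- S[2, 2]; gam <- S[1, 2]
  H <- decomp$H
  h11t <- H[, 1, 1] + (gam / Sig) * H[, 1, 2]
  h22t <- H[, 2, 2] + (gam / Gam) * H[, 2, 1]
  intr1 <- Re(h11t * Conj(h11t)) * Sig
  intr2 <- Re(h22t * Conj(h22t)) * Gam
  gc_fwd <- log(s22 / intr2)
  gc_bwd <- log(s11 / intr1)
  inst <- log(intr1 * intr2 / detq)

  out <- tibble::tibble(
    frequency = Q$freq,
    coherence = C,
    transformed_coherence = fij,
    gc_forward = gc_fwd,
    gc_backward = gc_bwd,
    total_gc = gc_fwd + gc_bwd,
    instantaneous = inst,
    pct_instantaneous = ifelse(fij > 1e-12, 100 * inst / fij, NA_real_)
  )
  class(out) <- c("connectivity_spectra", class(out))
  attr(out, "factorization_residual") <- res
  attr(out, "decomposition_residual") <-
    max(abs(fij - (gc_fwd + gc_bwd + inst)))
  attr(out, "negative_instantaneous") <- any(inst < -1e-10)
  attr(out, "fs") <- Q$fs
  out
}

#' Percentage of transformed coherence due to instantaneous interaction
#'
#' `100 * instantaneous / transformed_coherence`, `NA` (flagged, not
#' fabricated) where the transformed coherence is zero.
#'
#' @param spectra A `connectivity_spectra` tibble from [granger_decompose()].
#' @return Numeric vector.
#' @export
pct_instantaneous <- function(spectra) {
  stopifnot(inherits(spectra, "connectivity_spectra"))
  spectra$pct_instantaneous
}

#' @describeIn granger_decompose One-row summary of a decomposition.
#' @param x A `connectivity_spectra`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.connectivity_spectra <- function(x, ...) {
  tibble::tibble(
    n_freq = nrow(x),
    mean_coherence = mean(x$coherence),
    mean_total_gc = mean(x$total_gc),
    mean_instantaneous = mean(x$instantaneous),
    decomposition_residual = attr(x, "decomposition_residual"),
    factorization_residual = attr(x, "factorization_residual") %||% NA_real_,
    negative_instantaneous = isTRUE(attr(x, "negative_instantaneous"))
  )
}

#' @describeIn granger_decompose Line plot of every spectrum, faceted by
#'   metric.
#' @param object A `connectivity_spectra`.
#' @exportS3Method ggplot2::autoplot
autoplot.connectivity_spectra <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              -"frequency",
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$frequency, y = .data$value)) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = if (is.null(attr(object, "fs"))) "frequency (rad/sample)"
             else "frequency (Hz)",
         y = NULL) +
    theme_minimal()
}

#' Export connectivity spectra as a long table and band-average summary
#'
#' @param spectra A `connectivity_spectra`.
#' @param path CSV path for the long table (`frequency, metric, value`).
#' @param json_path Optional JSON path for band averages.
#' @param bands Named list of `c(lo, hi)` frequency bands for the JSON
#'   summary.
#' @export
write_connectivity <- function(spectra, path, json_path = NULL,
                               bands = NULL) {
  long <- tidyr::pivot_longer(tibble::as_tibble(spectra), -"frequency",
                              names_to = "metric", values_to = "value")
  readr::write_csv(long, path)
  if (!is.null(json_path)) {
    bands <- bands %||% list(all = range(spectra$frequency))
    summ <- lapply(bands, function(b) {
      sel <- spectra$frequency >= b[1] & spectra$frequency <= b[2]
      as.list(colMeans(spectra[sel, setdiff(names(spectra), "frequency")],
                       na.rm = TRUE))
    })
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
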