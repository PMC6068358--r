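#' Common-signal power specification
#'
#' Describes the power spectrum \eqn{U(\omega)U^*(\omega)} of a signal shared
#' across channels (a non-silent reference, or a volume-conducted source).
#' Three kinds are supported: a frequency-flat level, a 1/f-like spectrum
#' \eqn{k / (\omega + \omega_0)} (the small offset \eqn{\omega_0} avoids the
#' \eqn{\omega = 0} singularity), and a custom per-frequency vector.
#'
#' @param kind `"flat"`, `"one_over_f"` or `"custom"`.
#' @param level Scalar power for `"flat"`.
#' @param k,omega0 Scale and offset (radians/sample) for `"one_over_f"`.
#' @param values Nonnegative per-frequency power vector for `"custom"`.
#' @return An object of class `common_signal_spec`.
#' @examples
#' u <- common_signal_spec("flat", level = 1)
#' common_signal_power(u, frequency_grid(8))
#' @export
common_signal_spec <- function(kind = c("flat", "one_over_f", "custom"),
                               level = 1, k = 1, omega0 = 0.05, values = NULL) {
  kind <- match.arg(kind)
  if (kind == "flat" && (!is_scalar_number(level) || level < 0)) {
    abort("flat common signal needs a single nonnegative level")
  }
  if (kind == "one_over_f" && (k < 0 || omega0 <= 0)) {
    abort("one_over_f common signal needs k >= 0 and omega0 > 0")
  }
  if (kind == "custom") {
    if (is.null(values) || any(!is.finite(values)) || any(values < 0)) {
      abort("custom common signal needs a finite nonnegative power vector")
    }
  }
  structure(list(kind = kind, level = level, k = k, omega0 = omega0,
                 values = values),
            class = "common_signal_spec")
}

#' @rdname common_signal_spec
#' @param u A `common_signal_spec`.
#' @param freq Frequency grid on which to evaluate the power.
#' @param fs Sampling rate when `freq` is in Hz.
#' @export
common_signal_power <- function(u, freq, fs = NULL) {
  stopifnot(inherits(u, "common_signal_spec"))
  switch(u$kind,
    flat = rep(u$level, length(freq)),
    one_over_f = u$k / (grid_to_radians(freq, fs) + u$omega0),
    custom = {
      if (length(u$values) != length(freq)) {
        abort("custom common-signal power length must match the grid")
      }
      u$values
    }
  )
}

#' @rdname common_signal_spec
#' @param path JSON file path.
#' @export
common_signal_to_json <- function(u, path) {
  stopifnot(inherits(u, "common_signal_spec"))
  jsonlite::write_json(unclass(u), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname common_signal_spec
#' @export
common_signal_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  common_signal_spec(kind = x$kind, level = x$level %||% 1, k = x$k %||% 1,
                     omega0 = x$omega0 %||% 0.05, values = x$values)
}

#' Inject an independent common signal into a spectral matrix
#'
#' Adding a signal with power \eqn{U(\omega)U^*(\omega)} identically to all
#' channels, independently of the underlying process, adds that power to
#' *every* entry of the spectral density matrix. The independence of the
#' common signal from the neural process is an enforced assumption of this
#' operation.
#'
#' @param Q A [spectral_matrix()].
#' @param u A [common_signal_spec()], or a nonnegative per-frequency power
#'   vector (length matching the grid), or a single scalar level.
#' @return A [spectral_matrix()] with \eqn{Q^C(\omega) = Q(\omega) +
#'   U(\omega)U^*(\omega) \mathbf{1}\mathbf{1}^T}.
#' @examples
#' Q <- spectral_matrix(frequency_grid(4), array(rep(c(1,0,0,1), each = 4), c(4,2,2)))
#' Qc <- inject_common(Q, common_signal_spec("flat", level = 1))
#' Re(Qc$Q[1, , ]) # [[2,1],[1,2]]
#' @export
inject_common <- function(Q, u) {
  stopifnot(inherits(Q, "spectral_matrix"))
  if (inherits(u, "common_signal_spec")) {
    pw <- common_signal_power(u, Q$freq, fs = Q$fs)
  } else if (is.numeric(u) && length(u) == 1L) {
    pw <- rep(u, length(Q$freq))
  } else if (is.numeric(u)) {
    if (length(u) != length(Q$freq)) {
      abort("common-signal power length must match the frequency grid")
    }
    pw <- u
  } else {
    abort("u must be a common_signal_spec or a numeric power")
  }
  if (any(pw < 0)) abort("common-signal power must be nonnegative")
  out <- Q
  for (i in seq_len(Q$p)) for (j in seq_len(Q$p)) {
    out$Q[, i, j] <- out$Q[, i, j] + pw
  }
  out
}

#' NCR / coherence closed forms
#'
#' Under the assumptions that the neural signals are mutually independent at
#' the evaluated frequency, the common signal is independent of them, and the
#' neural-to-common-signal ratio (NCR) is equal across channels, coherence
#' and NCR are linked by \eqn{C = 1/(\mathrm{NCR}+1)^2}, hence
#' \eqn{\mathrm{NCR} = 1/\sqrt{C} - 1}.
#'
#' @param C Coherence value(s) in (0, 1].
#' @param ncr Nonnegative NCR value(s).
#' @return `ncr_from_coherence` returns NCR; `coherence_from_ncr` returns
#'   coherence in (0, 1]. Both carry an `assumptions` attribute naming the
#'   assumptions under which the mapping is exact.
#' @examples
#' ncr_from_coherence(0.5)  # ~0.41
#' coherence_from_ncr(1)    # 0.25
#' @export
ncr_from_coherence <- function(C) {
  if (any(!is.finite(C))) abort("coherence must be finite")
  if (any(C > 1)) abort("coherence cannot exceed 1")
  if (any(C <= 0)) {
    abort("NCR is unbounded at zero coherence; C must be in (0, 1]")
  }
  structure(1 / sqrt(C) - 1, assumptions = ncr_assumptions())
}

#' @rdname ncr_from_coherence
#' @export
coherence_from_ncr <- function(ncr) {
  if (any(!is.finite(ncr)) || any(ncr < 0)) abort("NCR must be nonnegative")
  structure(1 / (ncr + 1)^2, assumptions = ncr_assumptions())
}

ncr_assumptions <- function() {
  c("neural signals independent at the evaluated frequency",
    "common signal independent of the neural signals",
    "equal NCR across channels")
}

#' Coherence between bipolar derivations sharing a unipolar channel
#'
#' Two bipolar derivations built from a shared middle channel stay coherent
#' even when all neural signals are independent: the shared channel acts as a
#' common signal. With auto-spectral powers \eqn{P_i, P_{i+1}, P_{i+2}} the
#' coherence is \eqn{P_{i+1}^2 / ((P_i + P_{i+1})(P_{i+2} + P_{i+1}))},
#' bounded by 0.25 when the three powers are equal.
#'
#' @param p_outer1 Power of the first outer channel (\eqn{P_i}).
#' @param p_shared Power of the shared middle channel (\eqn{P_{i+1}}).
#' @param p_outer2 Power of the second outer channel (\eqn{P_{i+2}}).
#' @return Coherence value(s) in [0, 1].
#' @examples
#' shared_bipolar_coherence(1, 1, 1) # 0.25
#' @export
shared_bipolar_coherence <- function(p_outer1, p_shared, p_outer2) {
  if (any(c(p_outer1, p_shared, p_outer2) < 0)) {
    abort("powers must be nonnegative")
  }
  den1 <- p_outer1 + p_shared
  den2 <- p_outer2 + p_shared
  if (any(den1 == 0 | den2 == 0)) {
    abort("degenerate input: a bipolar derivation has zero power")
  }
  p_shared^2 / (den1 * den2)
}
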