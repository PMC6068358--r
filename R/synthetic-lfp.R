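#' Configuration for the synthetic linear-array LFP generator
#'
#' The generator emulates a fly-brain linear-probe preparation: 15 unipolar
#' channels at 25 um pitch sampled at 1000 Hz, 8 consecutive epochs of
#' 2.25 s. Each channel records
#' \deqn{y_i(t) = x_i(t) + vc_i(t) - r(t),}
#' where the neural signal \eqn{x_i = z_i + s_i} is the sum of a local
#' independent AR(1) stream \eqn{z_i} and a spatially correlated slow field
#' \eqn{s_i} (near-unit-root AR(1) driven by innovations with exponential
#' spatial correlation \eqn{\exp(-d/\lambda_n)}), \eqn{r} is a global
#' white reference signal subtracted from every channel, and
#' \eqn{vc_i = \sqrt{P_{vc}}\,e^{-|pos_i - pos_{src}|/\lambda_{vc}} s_{vc}(t)}
#' is a white volume-conducted source at the array centre with
#' distance-decaying amplitude. The slow field gives adjacent channels
#' highly similar low-frequency activity while leaving high frequencies
#' essentially independent.
#'
#' @param n_channels Number of unipolar channels (default 15).
#' @param fs_hz Sampling rate (default 1000).
#' @param n_epochs Number of epochs (default 8).
#' @param epoch_s Epoch duration in seconds (default 2.25).
#' @param pitch_um Electrode pitch (default 25).
#' @param local_ar,local_sd AR(1) coefficient and innovation sd of the local
#'   neural stream (defaults 0.8, 0.3).
#' @param slow_ar,slow_sd AR(1) coefficient and innovation sd of the shared
#'   slow field (defaults 0.97, 0.35). `slow_sd = 0` disables the field.
#' @param neural_lambda_um Spatial correlation length of the slow-field
#'   innovations (default 75).
#' @param reference_power Variance of the global reference signal r(t)
#'   (default 1).
#' @param vc_power Variance of the volume-conducted source (default 0.5).
#' @param vc_lambda_um Exponential decay length of the volume-conduction
#'   amplitude (default 100).
#' @param line_amp_50hz Amplitude of an optional 50 Hz line-noise sinusoid
#'   added identically to all channels (default 0).
#' @param seed Integer RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_channels = 15, fs_hz = 1000, n_epochs = 8,
                             epoch_s = 2.25, pitch_um = 25,
                             local_ar = 0.8, local_sd = 0.3,
                             slow_ar = 0.97, slow_sd = 0.35,
                             neural_lambda_um = 75,
                             reference_power = 1, vc_power = 0.5,
                             vc_lambda_um = 100, line_amp_50hz = 0,
                             seed = 1L) {
  cfg <- list(n_channels = n_channels, fs_hz = fs_hz, n_epochs = n_epochs,
              epoch_s = epoch_s, pitch_um = pitch_um, local_ar = local_ar,
              local_sd = local_sd, slow_ar = slow_ar, slow_sd = slow_sd,
              neural_lambda_um = neural_lambda_um,
              reference_power = reference_power, vc_power = vc_power,
              vc_lambda_um = vc_lambda_um, line_amp_50hz = line_amp_50hz,
              seed = as.integer(seed))
  if (cfg$n_channels < 2) abort("need at least two channels")
  if (cfg$reference_power < 0 || cfg$vc_power < 0 || cfg$line_amp_50hz < 0 ||
      cfg$local_sd < 0 || cfg$slow_sd < 0) {
    abort("variances and amplitudes must be nonnegative")
  }
  if (cfg$vc_lambda_um <= 0 || cfg$neural_lambda_um <= 0) {
    abort("decay lengths must be positive")
  }
  if (abs(cfg$epoch_s * cfg$fs_hz - round(cfg$epoch_s * cfg$fs_hz)) > 1e-9) {
    abort("epoch_s * fs_hz must be an integer number of samples")
  }
  if (max(abs(c(cfg$local_ar, cfg$slow_ar))) >= 1) {
    abort("AR coefficients must be inside the unit circle")
  }
  structure(cfg, class = "generator_config")
}

# analytic one-sided AR(1) spectrum, variance-normalized convention
ar1_psd <- function(phi, sd, w) sd^2 / (1 + phi^2 - 2 * phi * cos(w))

#' Generate a synthetic session with analytic ground truth
#'
#' Draws one multichannel recording from the generator model and returns it
#' together with the analytically derived (not estimated) ground truth:
#' per-frequency neural auto-spectra, common-signal power per channel
#' (reference plus volume-conduction contribution), and the implied
#' neural-to-common-signal ratio per channel per frequency. Deterministic
#' for a fixed `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List with elements `recording` (a [recording()]) and
#'   `ground_truth` (list: `freq_hz`, `neural_psd`, `common_psd`
#'   (channels x frequencies), `ncr` (channels x frequencies), `vc_amplitude`
#'   per channel, `config`).
#' @examples
#' sess <- generate_session(generator_config(n_channels = 3, n_epochs = 1,
#'                                           epoch_s = 0.5, seed = 2))
#' dim(sess$recording$samples)
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  n_per <- as.integer(round(cfg$epoch_s * cfg$fs_hz))
  n <- n_per * cfg$n_epochs
  burn <- 2000L
  ntot <- n + burn
  p <- cfg$n_channels
  positions <- (seq_len(p) - 1) * cfg$pitch_um
  dmat <- abs(outer(positions, positions, "-"))
  src_pos <- mean(positions)
  vc_amp <- sqrt(cfg$vc_power) * exp(-abs(positions - src_pos) / cfg$vc_lambda_um)

  samples <- with_seed(cfg$seed, function() {
    z <- vapply(seq_len(p), function(k) {
      as.numeric(stats::filter(rnorm(ntot, sd = cfg$local_sd), cfg$local_ar,
                               method = "recursive"))
    }, numeric(ntot))
    if (cfg$slow_sd > 0) {
      R <- exp(-dmat / cfg$neural_lambda_um)
      L <- t(chol(R + diag(1e-10, p)))
      e_s <- (matrix(rnorm(ntot * p), ntot, p) %*% t(L)) * cfg$slow_sd
      s <- vapply(seq_len(p), function(k) {
        as.numeric(stats::filter(e_s[, k], cfg$slow_ar, method = "recursive"))
      }, numeric(ntot))
    } else {
      s <- matrix(0, ntot, p)
    }
    r <- rnorm(ntot, sd = sqrt(cfg$reference_power))
    vsrc <- rnorm(ntot)
    y <- z + s + outer(vsrc, vc_amp) - matrix(r, ntot, p)
    if (cfg$line_amp_50hz > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      tt <- seq_len(ntot) / cfg$fs_hz
      y <- y + cfg$line_amp_50hz * sin(2 * pi * 50 * tt + ph)
    }
    y[(burn + 1):ntot, , drop = FALSE]
  })

  rec <- recording(samples, fs = cfg$fs_hz, positions = positions,
                   label = "unipolar", epoch_s = cfg$epoch_s,
                   n_epochs = cfg$n_epochs)

  nf <- n_per %/% 2L + 1L
  freq_hz <- seq(0, cfg$fs_hz / 2, length.out = nf)
  w <- 2 * pi * freq_hz / cfg$fs_hz
  neural_psd <- ar1_psd(cfg$local_ar, cfg$local_sd, w) +
    ar1_psd(cfg$slow_ar, cfg$slow_sd, w)
  common_psd <- t(vapply(seq_len(p), function(k) {
    rep(cfg$reference_power, nf) + vc_amp[k]^2
  }, numeric(nf)))
  ncr <- sweep(1 / common_psd, 2, neural_psd, "*")

  list(
    recording = rec,
    ground_truth = list(freq_hz = freq_hz, neural_psd = neural_psd,
                        common_psd = common_psd, ncr = ncr,
                        vc_amplitude = vc_amp, config = unclass(cfg))
  )
}

#' Ground-truth NCR aggregated over a frequency band
#'
#' Aggregates the analytic ground truth the same way the pipeline estimator
#' does: evaluates the closed-form coherence \eqn{1/(\mathrm{NCR}+1)^2} per
#' frequency, averages over the band, and inverts back to an NCR.
#'
#' @param ground_truth The `ground_truth` element of [generate_session()].
#' @param band `c(lo, hi)` in Hz.
#' @param channels Channels to average over (default all).
#' @return Scalar band-level ground-truth NCR.
#' @export
ground_truth_ncr <- function(ground_truth, band = c(200, 450),
                             channels = NULL) {
  gt <- ground_truth
  sel <- gt$freq_hz >= band[1] & gt$freq_hz <= band[2]
  channels <- channels %||% seq_len(nrow(gt$ncr))
  cbar <- mean(1 / (gt$ncr[channels, sel, drop = FALSE] + 1)^2)
  1 / sqrt(cbar) - 1
}

#' Time-domain recordings of the four simulation scenarios
#'
#' Generates two-channel realizations of the four canonical scenarios:
#' (1) unidirectionally connected, (2) disconnected with the connected
#' system's auto-spectra, (3) scenario 1 plus a flat-spectrum common signal,
#' (4) scenario 2 plus the same common signal. The common signal is white
#' noise whose power equals the mean neural power of the connected system
#' across the 0..Nyquist grid. The disconnected system is realized as two
#' independent streams whose marginal spectra match the connected system's:
#' channel 1 is the AR(1) source; channel 2 filters white noise with the
#' minimum-phase factor of \eqn{S_{22}} obtained by scalar Wilson
#' factorization.
#'
#' @param which Scenario number, 1-4.
#' @param n_samples Samples to generate.
#' @param seed Integer seed.
#' @param fs Sampling rate attached to the output (default 1000 Hz).
#' @param epoch_s Epoch length for the output's epoch structure; defaults to
#'   chopping the recording into 2.25 s epochs (truncated to fit).
#' @return A two-channel [recording()] (positions are nominal, 25 um apart).
#' @export
scenario_recording <- function(which, n_samples, seed = 1L, fs = 1000,
                               epoch_s = 2.25) {
  stopifnot(which %in% 1:4)
  model <- scenario_model("connected")
  uu <- mean_neural_power(ar_spectral_matrix(model))

  y <- with_seed(seed, function() {
    if (which %in% c(1, 3)) {
      out <- simulate_ar(model, n_samples, seed = NULL)
    } else {
      y1 <- as.numeric(stats::filter(rnorm(n_samples + 2000L), 0.1,
                                     method = "recursive"))[-(1:2000)]
      # minimum-phase filter matching the connected system's S22
      Qc <- ar_spectral_matrix(model, frequency_grid(513))
      s22 <- spectral_matrix(Qc$freq,
                             array(Qc$Q[, 2, 2], c(length(Qc$freq), 1, 1)),
                             validate = FALSE)
      td <- wilson_factorize(s22, full = TRUE)
      Hc <- attr(td, "H_circle")[, 1, 1]
      h <- Re(fft(Hc, inverse = TRUE)) / length(Hc)
      h <- h[1:min(length(h), 128L)]     # impulse response decays fast
      sdv <- sqrt(td$noise_cov[1, 1])
      wn <- rnorm(n_samples + length(h), sd = sdv)
      y2 <- as.numeric(stats::filter(wn, h, method = "convolution",
                                     sides = 1))
      y2 <- y2[(length(h) + 1):(length(h) + n_samples)]
      out <- cbind(y1, y2)
    }
    if (which %in% c(3, 4)) {
      out <- out + rnorm(n_samples, sd = sqrt(uu))
    }
    out
  })
  n_per <- as.integer(round(epoch_s * fs))
  n_ep <- max(1L, nrow(y) %/% n_per)
  if (nrow(y) < n_per) { epoch_s <- nrow(y) / fs; n_ep <- 1L }
  recording(y, fs = fs, positions = c(0, 25), label = "unipolar",
            epoch_s = epoch_s, n_epochs = n_ep)
}

#' Write a generated session to disk
#'
#' Writes the recording as CSV + JSON sidecar and the ground truth as JSON.
#'
#' @param session Output of [generate_session()].
#' @param path CSV path for the recording.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  write_recording(session$recording, path)
  gt <- session$ground_truth
  jsonlite::write_json(gt, paste0(path, ".ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
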