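#' Group channel pairs by electrode separation
#'
#' Assigns each channel pair to one of the separation bins used for
#' distance-resolved averaging: adjacent (25 um), short (50 um), mid
#' (75-150 um) and long distance (175-325 um). Pairs whose separation falls
#' outside all bins are excluded. Bin edges are exact array distances with a
#' +/- 1 um tolerance for user-supplied positions.
#'
#' @param positions Strictly increasing channel positions in micrometers.
#' @param bins Named list of `c(lo, hi)` separation ranges in micrometers.
#' @return Tibble with columns `i`, `j`, `separation_um`, `bin` (factor in
#'   bin order); one row per retained pair.
#' @examples
#' group_pairs(seq(0, by = 25, length.out = 15)) |> dplyr::count(bin)
#' @export
group_pairs <- function(positions,
                        bins = list("25" = c(25, 25), "50" = c(50, 50),
                                    "75-150" = c(75, 150),
                                    "175-325" = c(175, 325))) {
  p <- length(positions)
  if (p < 2) abort("need at least two channels")
  pr <- tidyr::expand_grid(i = seq_len(p), j = seq_len(p)) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(separation_um = abs(positions[.data$j] - positions[.data$i]))
  tol <- 1
  pr$bin <- NA_character_
  for (nm in names(bins)) {
    b <- bins[[nm]]
    hit <- is.na(pr$bin) & pr$separation_um >= b[1] - tol &
      pr$separation_um <= b[2] + tol
    pr$bin[hit] <- nm
  }
  pr <- dplyr::filter(pr, !is.na(.data$bin))
  pr$bin <- factor(pr$bin, levels = names(bins))
  pr
}

#' Channel-averaged power in decibels
#'
#' \eqn{\bar S(\omega) = \frac{1}{p}\sum_i 10\log_{10} S_{ii}(\omega)}:
#' the average is taken in the dB domain.
#'
#' @param Q A [spectral_matrix()] with strictly positive auto-spectra.
#' @return Tibble with columns `frequency`, `power_db`.
#' @export
power_summary <- function(Q) {
  stopifnot(inherits(Q, "spectral_matrix"))
  auto <- vapply(seq_len(Q$p), function(i) Re(Q$Q[, i, i]), numeric(length(Q$freq)))
  if (min(auto) <= 0) abort("power summary is undefined at zero auto-spectrum")
  tibble::tibble(frequency = Q$freq,
                 power_db = rowMeans(10 * log10(auto)))
}

#' Estimate the neural-to-common-signal ratio from high-frequency coherence
#'
#' Inverts the coherence/NCR closed form on a frequency band where genuine
#' neurophysiological coupling is not expected. Coherence is averaged over
#' the band per pair, debiased for the finite number of
#' taper-by-epoch estimates (`C - (1-C)^2/nu`, `nu = n_tapers * n_epochs`),
#' and mapped through `NCR = 1/sqrt(C) - 1`. By default only the
#' long-distance bin is used: those pairs are least affected by volume
#' conduction and genuine coupling, so the equal-common-signal assumptions
#' behind the closed form are most defensible there.
#'
#' @param Q A multichannel [spectral_matrix()] (epoch-averaged CSD).
#' @param pairs Pair table from [group_pairs()].
#' @param band `c(lo, hi)` frequency band in the grid's units
#'   (default 200-450 Hz).
#' @param use_bins Bins to include (default `"175-325"`).
#' @param nu Equivalent number of independent spectral estimates for the
#'   debias step; `NULL` skips debiasing.
#' @return Tibble with one row per pair (`i`, `j`, `bin`, `coherence_band`,
#'   `ncr`) and attributes `ncr_median`, `band`.
#' @export
estimate_ncr <- function(Q, pairs, band = c(200, 450),
                         use_bins = "175-325", nu = NULL) {
  stopifnot(inherits(Q, "spectral_matrix"))
  sel <- Q$freq >= band[1] & Q$freq <= band[2]
  if (!any(sel)) abort("NCR band contains no grid frequencies")
  use <- pairs[pairs$bin %in% use_bins, , drop = FALSE]
  if (nrow(use) == 0) abort("no pairs in the requested separation bins")
  cband <- purrr::map2_dbl(use$i, use$j, function(i, j) {
    c_ij <- Mod(Q$Q[sel, i, j])^2 /
      (Re(Q$Q[sel, i, i]) * Re(Q$Q[sel, j, j]))
    mean(c_ij)
  })
  if (!is.null(nu)) cband <- pmax(cband - (1 - cband)^2 / nu, 1e-6)
  out <- tibble::tibble(i = use$i, j = use$j, bin = use$bin,
                        coherence_band = cband,
                        ncr = 1 / sqrt(cband) - 1)
  attr(out, "ncr_median") <- median(out$ncr)
  attr(out, "band") <- band
  out
}

#' Full session analysis of a linear-array recording
#'
#' Runs the complete empirical pipeline on a unipolar recording and its
#' bipolar derivation: per-epoch preprocessing (optional line-noise removal,
#' linear detrend, z-score), multitaper cross-spectral estimation, epoch
#' averaging, channel-averaged power summaries, pairwise connectivity
#' (coherence and, optionally, the Granger/instantaneous decomposition via
#' Wilson factorization), separation-binned group averages, and an NCR
#' estimate from high-frequency unipolar coherence.
#'
#' @param rec A unipolar [recording()].
#' @param n_tapers Multitaper taper count (default 9).
#' @param remove_lines Remove line noise before detrending (default TRUE).
#' @param line_freqs Line frequencies in Hz.
#' @param ncr_band High-frequency band for the NCR estimate (Hz).
#' @param include_gc Compute the Granger decomposition per pair (Wilson
#'   factorization; the slow part of the pipeline). When FALSE only power
#'   and coherence are reported.
#' @param bins Separation bins, see [group_pairs()].
#' @return An object of class `session_report`: a list of tibbles —
#'   `power` (`signal_type`, `frequency`, `power_db`), `pair_spectra`
#'   (per-pair connectivity), `group_spectra` (bin-averaged), `ncr`
#'   (per-pair NCR) — plus `config` metadata.
#' @export
analyze_session <- function(rec, n_tapers = 9, remove_lines = TRUE,
                            line_freqs = c(50, 150), ncr_band = c(200, 450),
                            include_gc = TRUE,
                            bins = list("25" = c(25, 25), "50" = c(50, 50),
                                        "75-150" = c(75, 150),
                                        "175-325" = c(175, 325))) {
  stopifnot(inherits(rec, "recording"))
  recs <- list(unipolar = rec, bipolar = bipolar_derive(rec))

  csd <- lapply(recs, function(r) {
    eps <- recording_epochs(r)
    qs <- lapply(eps, function(ep) {
      if (remove_lines) ep <- remove_line_noise(ep, r$fs, line_freqs)
      ep <- preprocess_epoch(ep)
      multitaper_csd(ep, r$fs, n_tapers = n_tapers)
    })
    average_epochs(qs)
  })

  # power is summarized before the variance normalization: z-scoring
  # equalizes each channel's total power, which would make the
  # unipolar-vs-bipolar power comparison meaningless
  power <- purrr::imap_dfr(recs, function(r, nm) {
    qs <- lapply(recording_epochs(r), function(ep) {
      if (remove_lines) ep <- remove_line_noise(ep, r$fs, line_freqs)
      ep <- detrend_epoch(ep)
      multitaper_csd(ep, r$fs, n_tapers = n_tapers)
    })
    dplyr::mutate(power_summary(average_epochs(qs)), signal_type = nm,
                  .before = 1)
  })

  pair_tables <- purrr::imap(csd, function(q, nm) {
    pairs <- group_pairs(recs[[nm]]$positions, bins = bins)
    purrr::pmap_dfr(pairs, function(i, j, separation_um, bin) {
      sub <- spectral_matrix(q$freq, q$Q[, c(i, j), c(i, j), drop = FALSE],
                             fs = q$fs, validate = FALSE)
      if (include_gc) {
        sp <- granger_decompose(sub)
      } else {
        C <- coherence_spectrum(sub)
        sp <- tibble::tibble(frequency = sub$freq, coherence = C,
                             transformed_coherence = transform_coherence(C))
      }
      dplyr::mutate(tibble::as_tibble(sp), signal_type = nm, i = i, j = j,
                    separation_um = separation_um, bin = bin, .before = 1)
    })
  })
  pair_spectra <- dplyr::bind_rows(pair_tables)

  group_spectra <- pair_spectra |>
    tidyr::pivot_longer(-c("signal_type", "i", "j", "separation_um", "bin",
                           "frequency"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$signal_type, .data$bin, .data$frequency,
                    .data$metric) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     n_pairs = dplyr::n(), .groups = "drop")

  # NCR from the farthest separation bin that has pairs (least affected by
  # volume conduction and genuine coupling)
  pairs_u <- group_pairs(rec$positions, bins = bins)
  far_bin <- utils::tail(levels(droplevels(pairs_u$bin)), 1)
  ncr <- estimate_ncr(csd$unipolar, pairs_u, band = ncr_band,
                      use_bins = far_bin,
                      nu = n_tapers * rec$n_epochs)

  structure(
    list(power = power, pair_spectra = pair_spectra,
         group_spectra = group_spectra, ncr = ncr,
         config = list(n_tapers = n_tapers, remove_lines = remove_lines,
                       line_freqs = line_freqs, ncr_band = ncr_band,
                       include_gc = include_gc, bins = bins,
                       fs = rec$fs, n_epochs = rec$n_epochs,
                       epoch_s = rec$epoch_s)),
    class = "session_report"
  )
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %d pair spectra rows, NCR median %.3f\n",
              nrow(x$pair_spectra), attr(x$ncr, "ncr_median")))
  invisible(x)
}

#' @describeIn analyze_session One-row summary of a session report.
#' @param x A `session_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.session_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(dplyr::distinct(x$pair_spectra,
                                   .data$signal_type, .data$i, .data$j)),
    n_freq = length(unique(x$pair_spectra$frequency)),
    ncr_median = attr(x$ncr, "ncr_median"),
    fs = x$config$fs,
    n_epochs = x$config$n_epochs
  )
}

#' @describeIn analyze_session Bin-averaged spectra, colored by separation
#'   bin and faceted by metric and signal type.
#' @param object A `session_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.session_report <- function(object, ...) {
  ggplot(object$group_spectra,
         aes(x = .data$frequency, y = .data$value, colour = .data$bin)) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~ .data$signal_type + .data$metric, scales = "free_y") +
    labs(x = "frequency (Hz)", y = NULL, colour = "separation (µm)") +
    theme_minimal()
}

#' Write a session report to a directory
#'
#' Emits `power.csv`, `pair_spectra.csv`, `group_spectra.csv`, `ncr.csv` and
#' a `report.json` summary (config echo, NCR median).
#'
#' @param report A `session_report`.
#' @param dir Output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "session_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$power, file.path(dir, "power.csv"))
  readr::write_csv(report$pair_spectra, file.path(dir, "pair_spectra.csv"))
  readr::write_csv(report$group_spectra, file.path(dir, "group_spectra.csv"))
  readr::write_csv(tibble::as_tibble(report$ncr), file.path(dir, "ncr.csv"))
  jsonlite::write_json(
    list(ncr_median = attr(report$ncr, "ncr_median"),
         ncr_band = report$config$ncr_band,
         config = report$config[c("n_tapers", "remove_lines", "line_freqs",
                                  "include_gc", "fs", "n_epochs", "epoch_s")]),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
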