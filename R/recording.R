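#' Multichannel recording
#'
#' Container for a samples x channels matrix plus the metadata the analysis
#' pipeline needs: sampling rate, electrode positions along the linear array,
#' whether the channels are unipolar or bipolar, and the epoch structure.
#'
#' @param samples Numeric matrix, samples in rows, channels in columns.
#' @param fs Sampling rate (Hz).
#' @param positions Channel positions in micrometers along the array,
#'   strictly increasing, one per channel.
#' @param label `"unipolar"` or `"bipolar"`.
#' @param epoch_s Epoch length in seconds. `epoch_s * fs` must be an integer
#'   and `n_epochs * epoch_s * fs` must not exceed the number of samples.
#' @param n_epochs Number of consecutive epochs analyzed (from the start of
#'   the recording).
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, positions,
                      label = c("unipolar", "bipolar"),
                      epoch_s = NULL, n_epochs = NULL) {
  label <- match.arg(label)
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    abort("samples must be a finite numeric matrix",
          class = "commonsig_error_nonfinite")
  }
  if (!is_scalar_number(fs) || fs <= 0) abort("fs must be a positive scalar")
  positions <- as.numeric(positions)
  if (length(positions) != ncol(samples)) {
    abort("positions must have one entry per channel")
  }
  if (any(diff(positions) <= 0)) abort("positions must be strictly increasing")
  if (is.null(epoch_s)) {
    epoch_s <- nrow(samples) / fs
    n_epochs <- 1L
  }
  n_epochs <- as.integer(n_epochs %||% 1L)
  n_per <- epoch_s * fs
  if (abs(n_per - round(n_per)) > 1e-9) {
    abort("epoch_s * fs must be an integer number of samples")
  }
  if (round(n_per) * n_epochs > nrow(samples)) {
    abort("epoch structure exceeds the number of samples")
  }
  structure(
    list(samples = samples, fs = fs, positions = positions, label = label,
         epoch_s = epoch_s, n_epochs = n_epochs),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s, %d channels x %d samples @ %g Hz, %d epoch(s) of %gs\n",
              x$label, ncol(x$samples), nrow(x$samples), x$fs, x$n_epochs,
              x$epoch_s))
  invisible(x)
}

# list of epoch matrices (samples_per_epoch x channels)
recording_epochs <- function(rec) {
  n_per <- as.integer(round(rec$epoch_s * rec$fs))
  lapply(seq_len(rec$n_epochs), function(e) {
    rec$samples[((e - 1) * n_per + 1):(e * n_per), , drop = FALSE]
  })
}

#' Bipolar derivation of a unipolar recording
#'
#' Subtracts each channel's nearest neighbor along the array:
#' channel i of the output is `y_i - y_{i+1}`. Any signal contributed
#' identically to adjacent channels (e.g., a non-silent reference) cancels
#' exactly. Output positions are the midpoints of the contributing pairs.
#'
#' @param rec A [recording()] with at least 2 channels.
#' @return A [recording()] with one fewer channel and label `"bipolar"`.
#' @examples
#' r <- recording(cbind(rnorm(100), rnorm(100)), fs = 100, positions = c(0, 25))
#' bipolar_derive(r)
#' @export
bipolar_derive <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  p <- ncol(rec$samples)
  if (p < 2) abort("bipolar derivation needs at least two channels")
  s <- rec$samples[, -p, drop = FALSE] - rec$samples[, -1, drop = FALSE]
  pos <- (rec$positions[-p] + rec$positions[-1]) / 2
  recording(s, rec$fs, pos, label = "bipolar",
            epoch_s = rec$epoch_s, n_epochs = rec$n_epochs)
}

#' Write / read a recording as delimited text plus a JSON sidecar
#'
#' The samples go to a comma-separated UTF-8 file with a mandatory header row
#' of channel labels; the metadata (`fs_hz`, `positions_um`, `label`,
#' `epoch_s`, `n_epochs`, `reference`) goes to a JSON sidecar. Values are
#' written with enough digits for an exact round trip.
#'
#' @param rec A [recording()].
#' @param path CSV file path.
#' @param sidecar_path JSON sidecar path; defaults to `path` with a `.json`
#'   extension appended.
#' @param reference Free-text tag for the reference electrode site
#'   (e.g. `"thorax"`).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, path, sidecar_path = paste0(path, ".json"),
                            reference = "thorax") {
  stopifnot(inherits(rec, "recording"))
  d <- as.data.frame(rec$samples)
  names(d) <- sprintf("ch%02d", seq_len(ncol(d)))
  readr::write_csv(d, path)
  jsonlite::write_json(
    list(fs_hz = rec$fs, positions_um = rec$positions, label = rec$label,
         epoch_s = rec$epoch_s, n_epochs = rec$n_epochs,
         reference = reference),
    sidecar_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, sidecar_path = paste0(path, ".json")) {
  if (!file.exists(path)) {
    abort(sprintf("recording file not found: %s", path),
          class = "commonsig_error_missing_file")
  }
  if (!file.exists(sidecar_path)) {
    abort(sprintf("JSON sidecar not found: %s", sidecar_path),
          class = "commonsig_error_missing_sidecar")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("fs_hz", "positions_um", "label")) {
    if (is.null(meta[[field]])) {
      abort(sprintf("sidecar is missing required field '%s'", field),
            class = "commonsig_error_bad_sidecar")
    }
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(d) != length(meta$positions_um)) {
    abort(sprintf("header has %d channels but sidecar lists %d positions",
                  ncol(d), length(meta$positions_um)),
          class = "commonsig_error_bad_header")
  }
  m <- as.matrix(d)
  if (!is.numeric(m) || any(!is.finite(m))) {
    abort("recording contains non-numeric or non-finite samples",
          class = "commonsig_error_nonfinite")
  }
  recording(m, fs = meta$fs_hz, positions = meta$positions_um,
            label = meta$label, epoch_s = meta$epoch_s %||% NULL,
            n_epochs = meta$n_epochs %||% NULL)
}
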