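#' Zero-phase band-pass filtering
#'
#' Filters every channel of a continuous recording with a Butterworth
#' band-pass applied forward and backward (`signal::filtfilt`), so the output
#' has no group delay and phase estimates downstream are undistorted.
#' Filtering is done on the continuous recording, before segmentation, to
#' keep per-epoch edge transients out of the phase series.
#'
#' @param recording An [eeg_recording()].
#' @param band A band name from [eeg_bands()] or numeric `c(low, high)` in Hz.
#' @param order Butterworth design order (applied twice by the
#'   forward-backward pass).
#' @return A filtered [eeg_recording()].
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 1024), 2), fs = 128)
#' bandpass(rec, "alpha2")
bandpass <- function(recording, band, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  band <- resolve_band(band)
  nyq <- recording$fs / 2
  if (band$high >= nyq) {
    stop(sprintf("band [%g, %g] Hz violates Nyquist at fs = %g Hz",
                 band$low, band$high, recording$fs), call. = FALSE)
  }
  bf <- signal::butter(order, c(band$low, band$high) / nyq, type = "pass")
  out <- cpp_filtfilt(bf$b, bf$a, recording$data)
  res <- eeg_recording(out, fs = recording$fs,
                       channel_labels = recording$channel_labels)
  attr(res, "provenance") <- attr(recording, "provenance")
  attr(res, "band") <- band
  res
}

#' Broadband pre-filter
#'
#' The standard broadband cleanup stage (default 0.5-50 Hz) that removes very
#' low-frequency drift and line noise before band-specific analysis.
#'
#' @inheritParams bandpass
#' @param low,high Pass-band edges in Hz.
#' @return A filtered [eeg_recording()].
#' @export
prefilter <- function(recording, low = 0.5, high = 50, order = 4) {
  bandpass(recording, c(low, high), order = order)
}

#' Re-reference to the mean of named channels
#'
#' Optional linear re-referencing hook: subtracts the across-time mean signal
#' of the named reference channels from every channel.
#'
#' @inheritParams bandpass
#' @param ref_channels Character vector of channel labels to average.
#' @return A re-referenced [eeg_recording()].
#' @export
rereference <- function(recording, ref_channels) {
  stopifnot(inherits(recording, "eeg_recording"))
  idx <- match(ref_channels, recording$channel_labels)
  if (anyNA(idx)) {
    stop("unknown reference channel(s): ",
         paste(ref_channels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ref <- colMeans(recording$data[idx, , drop = FALSE])
  out <- sweep(recording$data, 2, ref)
  eeg_recording(out, fs = recording$fs,
                channel_labels = recording$channel_labels)
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of
#' `epoch_len_s` seconds; a trailing partial epoch is discarded. A six-minute
#' recording at any sampling rate yields 180 two-second epochs.
#'
#' @param recording An [eeg_recording()].
#' @param epoch_len_s Epoch length in seconds (default 2 s).
#' @return An object of class `eeg_epochs`: `data` is an
#'   epochs x channels x samples array, `kept` a logical mask (all `TRUE`
#'   after segmentation).
#' @export
segment_epochs <- function(recording, epoch_len_s = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  spl <- round(epoch_len_s * recording$fs)
  total <- ncol(recording$data)
  if (total < spl) {
    stop(sprintf("recording (%.3g s) is shorter than one epoch (%.3g s)",
                 total / recording$fs, epoch_len_s), call. = FALSE)
  }
  n_ep <- floor(total / spl)
  arr <- array(NA_real_, dim = c(n_ep, nrow(recording$data), spl))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- recording$data[, ((e - 1) * spl + 1):(e * spl)]
  }
  structure(
    list(data = arr, channel_labels = recording$channel_labels,
         fs = recording$fs, epoch_len_s = epoch_len_s,
         kept = rep(TRUE, n_ep)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d epochs (%d kept) x %d channels x %d samples @ %g Hz\n",
    dim(x$data)[1], sum(x$kept), dim(x$data)[2], dim(x$data)[3], x$fs
  ))
  invisible(x)
}

#' Concatenate kept epochs back into a recording
#'
#' Inverse of [segment_epochs()] over the kept epochs; round-trips the kept
#' data exactly.
#'
#' @param epoched An `eeg_epochs`.
#' @return An [eeg_recording()].
#' @export
concatenate_epochs <- function(epoched) {
  stopifnot(inherits(epoched, "eeg_epochs"))
  keep <- which(epoched$kept)
  if (length(keep) == 0) stop("no kept epochs to concatenate", call. = FALSE)
  d <- dim(epoched$data)
  out <- matrix(NA_real_, d[2], length(keep) * d[3])
  for (k in seq_along(keep)) {
    out[, ((k - 1) * d[3] + 1):(k * d[3])] <- epoched$data[keep[k], , ]
  }
  eeg_recording(out, fs = epoched$fs, channel_labels = epoched$channel_labels)
}

#' Amplitude-based epoch rejection
#'
#' Marks as rejected every epoch whose absolute amplitude exceeds the
#' threshold at any channel and sample (default +/-150 microvolts). If fewer
#' than `min_epochs` epochs survive (the study's sufficiency rule is 80),
#' a warning is raised and the shortfall recorded in the `qc` attribute;
#' analysis can still proceed on small synthetic fixtures. The operation is
#' idempotent.
#'
#' @param epoched An `eeg_epochs`.
#' @param amp_threshold Rejection threshold in microvolts (positive).
#' @param min_epochs Minimum number of surviving epochs considered sufficient.
#' @return The `eeg_epochs` with an updated `kept` mask and a `qc` attribute
#'   (tibble: epochs total, kept, rejected, sufficient).
#' @export
reject_epochs <- function(epoched, amp_threshold = 150, min_epochs = 80) {
  stopifnot(inherits(epoched, "eeg_epochs"))
  if (!is.numeric(amp_threshold) || amp_threshold <= 0) {
    stop("`amp_threshold` must be positive", call. = FALSE)
  }
  n_ep <- dim(epoched$data)[1]
  bad <- vapply(seq_len(n_ep), function(e) {
    any(abs(epoched$data[e, , ]) > amp_threshold)
  }, logical(1))
  epoched$kept <- epoched$kept & !bad
  qc <- tibble::tibble(
    epochs_total = n_ep,
    epochs_kept = sum(epoched$kept),
    epochs_rejected = n_ep - sum(epoched$kept),
    sufficient = sum(epoched$kept) >= min_epochs
  )
  attr(epoched, "qc") <- qc
  if (!qc$sufficient) {
    warning(sprintf("only %d epochs survive rejection (minimum %d)",
                    qc$epochs_kept, min_epochs), call. = FALSE)
  }
  epoched
}

#' Band power of an epoched recording
#'
#' Mean band-limited power over kept epochs and channels: per epoch and
#' channel the one-sided periodogram is integrated over `[low, high]`
#' (epochs act as the averaging segments of a Welch estimate with a
#' rectangular window), then averaged. A unit-amplitude sinusoid inside the
#' band has power 0.5 (its mean square); power scales quadratically with
#' amplitude.
#'
#' @param epoched An `eeg_epochs` (already or not band-filtered; power is
#'   computed in the requested band either way).
#' @param band Band name or numeric `c(low, high)` in Hz.
#' @return A scalar: mean band power (microvolts squared).
#' @export
band_power <- function(epoched, band) {
  stopifnot(inherits(epoched, "eeg_epochs"))
  band <- resolve_band(band)
  keep <- which(epoched$kept)
  if (length(keep) == 0) stop("no kept epochs", call. = FALSE)
  d <- dim(epoched$data)
  N <- d[3]
  freqs <- (seq_len(floor(N / 2))) * epoched$fs / N
  sel <- which(freqs >= band$low & freqs <= band$high)
  if (length(sel) == 0) {
    stop("no frequency bins inside the band at this epoch length", call. = FALSE)
  }
  big <- matrix(0, N, length(keep) * d[2])
  for (k in seq_along(keep)) {
    big[, ((k - 1) * d[2] + 1):(k * d[2])] <-
      t(matrix(epoched$data[keep[k], , ], d[2], N))
  }
  X <- mvfft(big)
  # one-sided power: 2 |X_k|^2 / N^2 for 0 < k < N/2 (the Nyquist bin, if
  # included in `sel`, is not doubled)
  P <- 2 * Mod(X[sel + 1, , drop = FALSE])^2 / N^2
  if (N %% 2 == 0 && (N / 2) %in% sel) {
    P[sel == N / 2, ] <- P[sel == N / 2, ] / 2
  }
  mean(colSums(P))
}
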