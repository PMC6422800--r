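#' Multichannel recording container
#'
#' A continuous multichannel signal: a channels x samples numeric matrix with
#' channel labels and a sampling rate. Amplitudes are in microvolts.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of channel names; defaults to the
#'   matrix rownames or `ch1..chN`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (nrow(data) < 1) stop("recording has no channels", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- rownames(data)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(nrow(data)))
    }
  }
  if (length(channel_labels) != nrow(data)) {
    stop("one label per channel required", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording An `eeg_recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  ncol(recording$data) / recording$fs
}

#' Write / read a recording as delimited text
#'
#' Recordings are stored as tab-separated text with one header row of channel
#' labels and one row per sample, plus a JSON sidecar (`<path>.json`) holding
#' the sampling rate, duration and any generator provenance attached to the
#' recording.
#'
#' @param recording An `eeg_recording`.
#' @param path Output path for the delimited matrix.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  tbl <- as.data.frame(t(recording$data))
  names(tbl) <- recording$channel_labels
  utils::write.table(tbl, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  sidecar <- list(
    fs = recording$fs,
    n_channels = nrow(recording$data),
    n_samples = ncol(recording$data),
    duration_s = duration_s(recording)
  )
  prov <- attr(recording, "provenance")
  if (!is.null(prov)) sidecar$provenance <- prov
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param fs Sampling rate override; if `NULL` it is taken from the JSON
#'   sidecar next to `path`.
#' @export
read_recording <- function(path, fs = NULL) {
  if (is.null(fs)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("no `fs` given and no sidecar found at ", sidecar, call. = FALSE)
    }
    fs <- jsonlite::read_json(sidecar)$fs
  }
  tbl <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  eeg_recording(t(as.matrix(tbl)), fs = fs, channel_labels = names(tbl))
}
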