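#' Standard 64-channel montage
#'
#' Channel labels of the 64-electrode 10-20-derived montage used as the
#' default scalp layout, in the numbering order of the recording system
#' (channel 1 = FP1, ..., channel 64 = Oz). Regional results (e.g. hubs at
#' O1 or C4) are addressed by these names.
#'
#' @return Character vector of 64 channel labels.
#' @export
#' @examples
#' head(montage_1020_64())
montage_1020_64 <- function() {
  c(
    "FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T7", "T8", "P7", "P8", "Fz", "Cz", "Pz", "IO",
    "FC1", "FC2", "CP1", "CP2", "FC5", "FC6", "CP5", "CP6", "FT9", "FT10",
    "TP9", "TP10", "F1", "F2", "C1", "C2", "P1", "P2", "AF3", "AF4",
    "FC3", "FC4", "CP3", "CP4", "PO3", "PO4", "F5", "F6", "C5", "C6",
    "P5", "P6", "AF7", "AF8", "FT7", "FT8", "TP7", "TP8", "PO7", "PO8",
    "FPz", "CPz", "POz", "Oz"
  )
}

#' Default frequency bands
#'
#' The six canonical resting-state EEG bands used throughout the pipeline:
#' delta 0.5-4 Hz, theta 4-8 Hz, alpha1 8-10 Hz, alpha2 10-13 Hz,
#' beta 13-25 Hz, gamma 25-49 Hz.
#'
#' @param names Optional character vector to subset the table (in the given
#'   order).
#' @return A tibble with columns `band`, `low`, `high` (Hz).
#' @export
#' @examples
#' eeg_bands()
#' eeg_bands("alpha2")
eeg_bands <- function(names = NULL) {
  tbl <- tibble::tibble(
    band = c("delta", "theta", "alpha1", "alpha2", "beta", "gamma"),
    low  = c(0.5, 4, 8, 10, 13, 25),
    high = c(4, 8, 10, 13, 25, 49)
  )
  if (is.null(names)) return(tbl)
  missing <- setdiff(names, tbl$band)
  if (length(missing) > 0) {
    stop("unknown band(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl[match(names, tbl$band), ]
}

# Resolve a band given either a name from eeg_bands() or a numeric c(low, high).
resolve_band <- function(band) {
  if (is.character(band) && length(band) == 1) {
    row <- eeg_bands(band)
    return(list(name = row$band, low = row$low, high = row$high))
  }
  if (is.numeric(band) && length(band) == 2) {
    if (!(band[1] > 0 && band[1] < band[2])) {
      stop("band edges must satisfy 0 < low < high", call. = FALSE)
    }
    return(list(name = paste0(band[1], "-", band[2], "Hz"),
                low = band[1], high = band[2]))
  }
  stop("`band` must be a band name or numeric c(low, high)", call. = FALSE)
}
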