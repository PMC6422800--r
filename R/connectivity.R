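#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x Numeric matrix, channels x samples (band-limited).
#' @return Complex matrix of the same shape.
#' @keywords internal
analytic_signal <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  N <- ncol(x)
  X <- mvfft(t(x))
  t(mvfft(X * analytic_weights(N), inverse = TRUE)) / N
}

# one-sided spectral weights of the analytic-signal construction
analytic_weights <- function(N) {
  h <- numeric(N)
  if (N %% 2 == 0) {
    h[1] <- 1; h[N / 2 + 1] <- 1
    h[2:(N / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((N + 1) / 2)] <- 2
  }
  h
}

#' Instantaneous phase of band-limited signals
#'
#' Phase of the analytic signal per channel, in (-pi, pi]. Input is assumed
#' already band-filtered; constant (zero-variance) channels have no defined
#' phase and are returned as `NA` with a warning.
#'
#' @param x Numeric matrix, channels x samples (one epoch).
#' @return Numeric matrix of phases (radians), channels x samples.
#' @export
instantaneous_phase <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  flat <- apply(x, 1, function(r) diff(range(r)) == 0)
  ph <- Arg(analytic_signal(x))
  if (any(flat)) {
    warning(sprintf("%d constant channel(s): phase undefined, set to NA",
                    sum(flat)), call. = FALSE)
    ph[flat, ] <- NA_real_
  }
  ph
}

#' Phase lag index of a channel pair
#'
#' The PLI of two phase series is the absolute mean of the signum of the
#' sine of their phase difference: `|mean(sign(sin(phi_i - phi_j)))|`. It
#' quantifies the asymmetry of the phase-difference distribution around zero
#' (mod pi) and ranges from 0 (symmetric, e.g. zero-lag/volume-conducted
#' coupling) to 1 (a consistent nonzero lag). Exact zeros of the sine
#' contribute 0, exactly as the signum implies.
#'
#' @param phase_i,phase_j Equal-length numeric phase series (radians).
#' @return A scalar in \[0, 1\].
#' @export
#' @examples
#' pli_pair(rep(pi / 2, 100), rep(0, 100)) # constant quadrature lag -> 1
#' pli_pair(rep(0.3, 100), rep(0.3, 100))  # zero lag -> 0
pli_pair <- function(phase_i, phase_j) {
  if (length(phase_i) != length(phase_j)) {
    stop("phase series must have equal length", call. = FALSE)
  }
  if (length(phase_i) == 0) stop("empty phase series", call. = FALSE)
  s <- sign(sin(phase_i - phase_j))
  abs(mean(s))
}

new_pli_matrix <- function(values, channel_labels, band, epoch_index,
                           n_epochs_averaged = 1L) {
  dimnames(values) <- list(channel_labels, channel_labels)
  structure(values, class = c("pli_matrix", "matrix"),
            band = band, epoch_index = epoch_index,
            n_epochs_averaged = n_epochs_averaged)
}

#' @export
print.pli_matrix <- function(x, ...) {
  cat(sprintf("<pli_matrix> %d x %d, band %s, epoch %s\n",
              nrow(x), ncol(x),
              if (is.null(attr(x, "band"))) "?" else attr(x, "band"),
              as.character(attr(x, "epoch_index"))))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], ...)
  invisible(x)
}

#' Per-epoch PLI connectivity matrices
#'
#' Computes one symmetric zero-diagonal PLI matrix per kept epoch from the
#' instantaneous phases of the (band-filtered) epoch data. The first and last
#' `edge_trim` fraction of samples of each epoch are excluded from the signum
#' average to blunt Hilbert edge effects. With `pooled = TRUE` the trimmed
#' phase series of all kept epochs are concatenated and a single matrix is
#' returned.
#'
#' @param epoched An `eeg_epochs` whose data are band-filtered.
#' @param band Optional band tag carried in the output (name or `c(low,
#'   high)`).
#' @param edge_trim Fraction of samples trimmed from each end of every epoch
#'   (default 0.05; set 0 to disable).
#' @param pooled Concatenate epochs into one estimate instead of one matrix
#'   per epoch.
#' @return A list of `pli_matrix` objects (length = number of kept epochs),
#'   or a single `pli_matrix` if `pooled = TRUE`.
#' @export
pli_matrix <- function(epoched, band = NULL, edge_trim = 0.05,
                       pooled = FALSE) {
  stopifnot(inherits(epoched, "eeg_epochs"))
  keep <- which(epoched$kept)
  if (length(keep) == 0) stop("no kept epochs", call. = FALSE)
  if (edge_trim < 0 || edge_trim >= 0.5) {
    stop("`edge_trim` must lie in [0, 0.5)", call. = FALSE)
  }
  band_tag <- if (is.null(band)) {
    b <- attr(epoched, "band")
    if (is.null(b)) NA_character_ else b$name
  } else {
    resolve_band(band)$name
  }
  d <- dim(epoched$data)
  N <- d[3]
  trim <- floor(edge_trim * N)
  sel <- (trim + 1):(N - trim)
  flat <- vapply(seq_len(d[2]), function(c_) {
    all(epoched$data[keep, c_, ] == epoched$data[keep[1], c_, 1])
  }, logical(1))
  if (any(flat)) {
    warning(sprintf("%d constant channel(s): PLI undefined there",
                    sum(flat)), call. = FALSE)
  }
  # PLI needs only sign(sin(delta-phi)) = sign(Im(z_i conj(z_j))), so the
  # analytic signal is used directly (exactly equivalent to the explicit
  # phase-difference route; see pli_pair). All kept epochs and channels are
  # transformed in a single batched FFT (samples x (epoch*channel)).
  big <- matrix(0, N, length(keep) * d[2])
  for (k in seq_along(keep)) {
    big[, ((k - 1) * d[2] + 1):(k * d[2])] <-
      t(matrix(epoched$data[keep[k], , ], d[2], N))
  }
  h <- analytic_weights(N)
  Z <- mvfft(mvfft(big) * h, inverse = TRUE) / N
  analytic_of <- function(k) {
    t(Z[sel, ((k - 1) * d[2] + 1):(k * d[2]), drop = FALSE])
  }
  if (pooled) {
    z <- do.call(cbind, lapply(seq_along(keep), analytic_of))
    return(new_pli_matrix(cpp_pli_from_analytic(Re(z), Im(z)),
                          epoched$channel_labels, band_tag, "pooled",
                          length(keep)))
  }
  lapply(seq_along(keep), function(k) {
    z <- analytic_of(k)
    new_pli_matrix(cpp_pli_from_analytic(Re(z), Im(z)),
                   epoched$channel_labels, band_tag, keep[k])
  })
}

#' Average PLI matrices across epochs
#'
#' Element-wise mean of per-epoch connectivity matrices.
#'
#' @param matrices A list of `pli_matrix` objects of identical shape.
#' @return A single `pli_matrix` tagged `"averaged"`.
#' @export
average_pli <- function(matrices) {
  if (inherits(matrices, "pli_matrix")) matrices <- list(matrices)
  if (length(matrices) == 0) stop("no matrices to average", call. = FALSE)
  dims <- vapply(matrices, function(m) dim(m), integer(2))
  if (any(dims != dims[, 1])) {
    stop("matrices have heterogeneous shapes", call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(matrices, unclass))
  new_pli_matrix(acc / length(matrices),
                 rownames(matrices[[1]]),
                 attr(matrices[[1]], "band"), "averaged",
                 length(matrices))
}

#' Global PLI of a connectivity matrix
#'
#' Mean of the n(n-1)/2 upper-triangle entries: the participant's overall
#' functional connectivity level in a band.
#'
#' @param matrix A `pli_matrix` (or plain symmetric matrix).
#' @return A scalar in \[0, 1\].
#' @export
global_pli <- function(matrix) {
  m <- unclass(matrix)
  mean(m[upper.tri(m)])
}
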