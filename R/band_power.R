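#' EEG band-power time courses on the TR grid
#'
#' A cleaned multichannel EEG recording is variance normalized, cut into
#' consecutive TR-aligned epochs (one per fMRI volume), and each epoch is
#' taken to the frequency domain by FFT. Squared-magnitude spectral power is
#' averaged within each frequency band, yielding one epochs x channels
#' power matrix per band. For correlation against BOLD signals the power
#' time courses are convolved with a canonical double-gamma hemodynamic
#' response function sampled on the TR grid.
#'
#' @name band_power
NULL

#' Variance-normalize EEG channels
#'
#' Removes each channel's mean and scales it to unit sample variance
#' (divisor n - 1), over the full recording.
#'
#' @param x matrix channels x samples.
#' @return matrix of the same shape; each row has mean 0 and variance 1.
#' @export
variance_normalize <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  mu <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    lab <- rownames(x)[zero]
    if (is.null(lab)) lab <- which(zero)
    stop("zero-variance channel(s): ", paste(lab, collapse = ", "))
  }
  (x - mu) / s
}

#' Segment a recording into consecutive TR-aligned epochs
#'
#' Epoch k (0-based) covers samples `[k*fs*epoch_seconds,
#' (k+1)*fs*epoch_seconds)`; trailing surplus samples are discarded.
#'
#' @param x matrix channels x samples.
#' @param fs sampling rate in Hz.
#' @param epoch_seconds epoch length in seconds.
#' @param n_epochs number of epochs required; defaults to as many as fit.
#' @return array epochs x channels x samples_per_epoch.
#' @export
segment_epochs <- function(x, fs, epoch_seconds, n_epochs = NULL) {
  stopifnot(is.matrix(x), fs > 0, epoch_seconds > 0)
  spe <- as.integer(round(fs * epoch_seconds))
  avail <- ncol(x) %/% spe
  if (is.null(n_epochs)) n_epochs <- avail
  if (avail < n_epochs) {
    stop("too few samples: ", n_epochs, " epochs of ", spe,
         " samples requested, only ", avail, " available")
  }
  out <- array(0, dim = c(n_epochs, nrow(x), spe),
               dimnames = list(NULL, rownames(x), NULL))
  for (k in seq_len(n_epochs)) {
    out[k, , ] <- x[, ((k - 1L) * spe + 1L):(k * spe), drop = FALSE]
  }
  out
}

#' Average spectral power of each epoch within a frequency band
#'
#' Discrete-Fourier power (squared magnitude of the one-sided FFT) averaged
#' over the bins whose frequency falls in `[band_low, band_high)`; set
#' `closed_top = TRUE` for the final band of a partition so the top edge is
#' included.
#'
#' @param epochs array epochs x channels x samples (from
#'   [segment_epochs()]).
#' @param fs sampling rate in Hz.
#' @param band_low,band_high band edges in Hz, inside (0, fs/2].
#' @param closed_top include bins at exactly `band_high`.
#' @return matrix epochs x channels of non-negative band power.
#' @export
epoch_band_power <- function(epochs, fs, band_low, band_high,
                             closed_top = FALSE) {
  stopifnot(length(dim(epochs)) == 3, band_low > 0, band_high > band_low,
            band_high <= fs / 2)
  d <- dim(epochs)
  n <- d[3]
  half <- n %/% 2L
  freq <- (1L:half) * fs / n
  sel <- if (closed_top) freq >= band_low & freq <= band_high
         else freq >= band_low & freq < band_high
  if (!any(sel)) {
    stop("band [", band_low, ", ", band_high, ") Hz contains no FFT bin ",
         "at resolution ", fs / n, " Hz")
  }
  flat <- matrix(aperm(epochs, c(3L, 1L, 2L)), nrow = n)
  X <- stats::mvfft(flat)
  p <- 2 * Mod(X[1L + which(sel), , drop = FALSE])^2 / n^2
  bp <- colMeans(p)
  matrix(bp, nrow = d[1], ncol = d[2], dimnames = list(NULL, dimnames(epochs)[[2]]))
}

#' Band-power time courses for a full band set
#'
#' Convenience wrapper: variance normalization, epoching, and per-band
#' power, following the band order of the configuration. The last band of
#' the list is closed at its top edge; interior edges are half-open so
#' adjacent bands never share a bin.
#'
#' @param eeg matrix channels x samples.
#' @param fs sampling rate in Hz.
#' @param config [pipeline_config()].
#' @param n_epochs epochs to produce (defaults to as many as fit).
#' @return named list of epochs x channels matrices, one per band.
#' @export
band_power_timecourses <- function(eeg, fs, config = pipeline_config(),
                                   n_epochs = NULL) {
  x <- variance_normalize(eeg)
  ep <- segment_epochs(x, fs, config$epoch_seconds, n_epochs)
  d <- dim(ep)
  n <- d[3]
  half <- n %/% 2L
  freq <- (1L:half) * fs / n
  # one FFT pass shared by all bands
  flat <- matrix(aperm(ep, c(3L, 1L, 2L)), nrow = n)
  p <- 2 * Mod(stats::mvfft(flat)[2L:(half + 1L), , drop = FALSE])^2 / n^2
  nb <- length(config$bands)
  out <- vector("list", nb)
  names(out) <- names(config$bands)
  for (i in seq_len(nb)) {
    b <- config$bands[[i]]
    sel <- if (i == nb) freq >= b[1] & freq <= b[2]
           else freq >= b[1] & freq < b[2]
    if (!any(sel)) {
      stop("band [", b[1], ", ", b[2], ") Hz contains no FFT bin ",
           "at resolution ", fs / n, " Hz")
    }
    out[[i]] <- matrix(colMeans(p[sel, , drop = FALSE]),
                       nrow = d[1], ncol = d[2],
                       dimnames = list(NULL, dimnames(ep)[[2]]))
  }
  out
}

#' Canonical double-gamma HRF sampled on the TR grid
#'
#' Difference of two gamma densities with the standard canonical
#' parameterization: response peak at 6 s, undershoot peak at 16 s, unit
#' dispersions, undershoot ratio 1/6. The kernel is peak-normalized to 1 so
#' convolution rescales rather than amplifies.
#'
#' @param tr_seconds sample spacing in seconds.
#' @param duration_seconds kernel support (>= 24 s; default 32 s).
#' @return numeric vector of `ceiling(duration/tr)` samples with attributes
#'   `tr_seconds` and `duration_seconds`.
#' @export
canonical_hrf <- function(tr_seconds, duration_seconds = 32) {
  stopifnot(tr_seconds > 0, duration_seconds >= 24)
  dg <- function(t) stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  t <- seq(0, duration_seconds - tr_seconds / 2, by = tr_seconds)
  # normalize by the continuous-time peak so kernels at different TRs are
  # samples of one function (peak value 1 regardless of the grid)
  peak <- stats::optimize(dg, c(0, 12), maximum = TRUE, tol = 1e-12)$objective
  h <- dg(t) / peak
  structure(h, tr_seconds = tr_seconds, duration_seconds = duration_seconds)
}

#' Causal convolution of power time courses with an HRF kernel
#'
#' Linear convolution truncated to the input length: output at epoch t
#' depends only on epochs 0..t.
#'
#' @param power matrix epochs x channels (or a vector).
#' @param kernel HRF kernel from [canonical_hrf()] (any numeric vector).
#' @return matrix of the same shape as `power`.
#' @export
convolve_hrf <- function(power, kernel) {
  vec <- is.null(dim(power))
  if (vec) power <- matrix(power, ncol = 1L)
  n <- nrow(power)
  if (length(kernel) > n) {
    stop("kernel length ", length(kernel), " exceeds series length ", n)
  }
  out <- apply(power, 2L, function(col) {
    convolve(col, rev(kernel), type = "open")[seq_len(n)]
  })
  out <- matrix(out, nrow = n, dimnames = dimnames(power))
  if (vec) out[, 1L] else out
}
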