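#' Post-processing of fMRI independent-component time courses
#'
#' Four steps, applied in order to each component column: (1) removal of
#' linear, quadratic and cubic trends; (2) multiple regression of the six
#' realignment parameters and their temporal derivatives; (3) despiking by
#' robust z-score with linear interpolation; (4) zero-phase Butterworth
#' band-pass filtering to 0.01-0.10 Hz.
#'
#' @name fmri_post
NULL

#' Remove polynomial trends
#'
#' Residual of a least-squares fit of polynomials up to `order` (including
#' the intercept), per column. Orthogonal polynomials keep the design
#' well-conditioned; the residual is identical to the raw-power fit.
#'
#' @param tc matrix time x components.
#' @param order highest polynomial order (default cubic).
#' @return matrix of residuals, same shape.
#' @export
detrend_poly <- function(tc, order = 3) {
  tc <- as.matrix(tc)
  n <- nrow(tc)
  if (n <= order + 1) {
    stop("time length ", n, " must exceed order + 1 = ", order + 1)
  }
  X <- cbind(1, stats::poly(seq_len(n), degree = order))
  res <- stats::lm.fit(X, tc)$residuals
  matrix(res, nrow = n, dimnames = dimnames(tc))
}

#' Regress out realignment parameters and their derivatives
#'
#' Residual after projecting out an intercept, the six motion parameters,
#' and their first differences (leading element of each derivative set to
#' 0): 13 regressors. Rank-deficient designs drop the dependent columns
#' with a warning naming them.
#'
#' @param tc matrix time x components.
#' @param motion matrix time x 6 realignment parameters.
#' @return matrix of residuals, same shape as `tc`.
#' @export
regress_nuisance <- function(tc, motion) {
  tc <- as.matrix(tc); motion <- as.matrix(motion)
  if (nrow(motion) != nrow(tc)) {
    stop("motion has ", nrow(motion), " rows but time courses have ", nrow(tc))
  }
  stopifnot(ncol(motion) == 6)
  dmot <- rbind(0, diff(motion))
  X <- cbind(intercept = 1, motion, dmot)
  colnames(X) <- c("intercept", paste0("mp", 1:6), paste0("dmp", 1:6))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    warning("rank-deficient nuisance design; dropping: ",
            paste(dropped, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  res <- stats::lm.fit(X, tc)$residuals
  matrix(res, nrow = nrow(tc), dimnames = dimnames(tc))
}

#' Despike by robust z-score
#'
#' Per column, points with |value - median| > `z_thresh` * 1.4826 * MAD are
#' replaced by linear interpolation between the nearest non-outlier
#' neighbours (edge outliers take the nearest non-outlier value). Columns
#' with MAD = 0 are left untouched.
#'
#' @param tc matrix time x components (>= 8 time points).
#' @param z_thresh robust z threshold (default 4).
#' @return list with `values` (despiked matrix) and `n_replaced` (integer
#'   per column).
#' @export
despike <- function(tc, z_thresh = 4) {
  tc <- as.matrix(tc)
  n <- nrow(tc)
  stopifnot(n >= 8)
  n_replaced <- integer(ncol(tc))
  out <- tc
  for (j in seq_len(ncol(tc))) {
    v <- tc[, j]
    med <- stats::median(v)
    mad_ <- stats::median(abs(v - med))
    if (mad_ == 0) next
    bad <- abs(v - med) > z_thresh * 1.4826 * mad_
    n_replaced[j] <- sum(bad)
    if (!any(bad)) next
    if (n_replaced[j] > 0.2 * n) {
      warning("column ", j, ": ", n_replaced[j], " of ", n,
              " points flagged as spikes (> 20%)")
    }
    good <- which(!bad)
    out[bad, j] <- stats::approx(good, v[good], xout = which(bad),
                                 rule = 2)$y
  }
  names(n_replaced) <- colnames(tc)
  list(values = out, n_replaced = n_replaced)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 5th-order Butterworth applied forward-backward (`signal::filtfilt`), so
#' the pass band is phase-neutral and the effective attenuation is doubled.
#'
#' @param tc matrix time x components (or a vector).
#' @param low,high band edges in Hz.
#' @param tr_seconds sample spacing in seconds (fs = 1/tr).
#' @param order filter order (default 5).
#' @return filtered matrix/vector, same shape.
#' @export
bandpass <- function(tc, low = 0.01, high = 0.10, tr_seconds = 2,
                     order = 5) {
  fs <- 1 / tr_seconds
  nyq <- fs / 2
  if (low <= 0 || high >= nyq || high <= low) {
    stop("band [", low, ", ", high, "] Hz outside (0, Nyquist = ", nyq, ")")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  vec <- is.null(dim(tc))
  if (vec) tc <- matrix(tc, ncol = 1L)
  # demean before filtering (the filter has a DC zero, but finite-length
  # edge transients leak a nonzero-mean input) and remove the residual
  # mean after, so filtered columns are exactly mean-free
  mu <- colMeans(tc)
  out <- apply(sweep(tc, 2L, mu), 2L, function(col) signal::filtfilt(bf, col))
  out <- matrix(out, nrow = nrow(tc), dimnames = dimnames(tc))
  out <- sweep(out, 2L, colMeans(out))
  if (vec) out[, 1L] else out
}

#' Full IC time-course post-processing
#'
#' Applies the four steps in order: detrend, nuisance regression (skipped
#' when `motion` is `NULL`), despike, band-pass.
#'
#' @param tc matrix time x components.
#' @param motion optional matrix time x 6.
#' @param config [pipeline_config()] supplying `tr_seconds` and
#'   `bandpass_hz`.
#' @param z_thresh despiking threshold.
#' @return matrix of cleaned time courses, same shape, with attribute
#'   `n_despiked`.
#' @export
postprocess_timecourses <- function(tc, motion = NULL,
                                    config = pipeline_config(),
                                    z_thresh = 4) {
  x <- detrend_poly(tc)
  if (!is.null(motion)) x <- regress_nuisance(x, motion)
  ds <- despike(x, z_thresh)
  out <- bandpass(ds$values, config$bandpass_hz[1], config$bandpass_hz[2],
                  config$tr_seconds)
  dimnames(out) <- dimnames(as.matrix(tc))
  attr(out, "n_despiked") <- ds$n_replaced
  out
}
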