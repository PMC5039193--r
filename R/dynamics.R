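#' Dynamic graph-metric time series and their summaries
#'
#' A dynamic graph sequence is reduced to one metric value per window
#' (connectivity strength, clustering, or efficiency; global or at one
#' node; on W+ or W-). The window series is summarized by its sample
#' variance, the amplitude of its low-frequency fluctuations (LFA, mean
#' one-sided DFT amplitude over (0, 0.025] Hz, DC excluded), its amplitude
#' spectrum, and a KPSS level-stationarity test. The series sampling rate
#' is 1/(step x TR): one window per TR at step 1.
#'
#' @name dynamics
NULL

#' Metric time series over a dynamic graph sequence
#'
#' @param seq `dynamic_graph_seq` from [sliding_windows()].
#' @param metric `"CS"`, `"CC"` or `"GE"`.
#' @param level `"global"` or a node label (or index).
#' @param sign `"positive"` (W+) or `"negative"` (W-).
#' @param denominator clustering denominator (see [nodal_clustering()]).
#' @return numeric vector, one value per window, with attribute
#'   `window_step_seconds` when the sequence carries `tr_seconds`.
#' @export
metric_series <- function(seq, metric = c("CS", "CC", "GE"),
                          level = "global", sign = c("positive", "negative"),
                          denominator = "degree") {
  metric <- match.arg(metric)
  sign <- match.arg(sign)
  stopifnot(inherits(seq, "dynamic_graph_seq"), length(seq$starts) >= 1)
  wkey <- if (sign == "positive") "w_plus" else "w_minus"
  labels <- rownames(seq$r[[1]])
  idx <- NULL
  if (!identical(level, "global")) {
    idx <- if (is.numeric(level)) as.integer(level) else match(level, labels)
    if (is.na(idx) || idx < 1 || idx > nrow(seq$r[[1]])) {
      stop("unknown node label: ", level)
    }
  }
  fn <- switch(metric,
               CS = nodal_strength,
               CC = function(w) nodal_clustering(w, denominator),
               GE = nodal_efficiency)
  vapply(seq$signed, function(sp) {
    v <- fn(sp[[wkey]])
    if (is.null(idx)) mean(v) else v[idx]
  }, numeric(1))
}

#' Sample variance of a window series
#'
#' @param series numeric vector (length >= 2).
#' @return sample variance (divisor n - 1).
#' @export
series_variance <- function(series) {
  if (length(series) < 2) stop("need >= 2 windows, got ", length(series))
  stats::var(series)
}

#' One-sided amplitude spectrum of a window series
#'
#' Mean-removed series; amplitudes `2 |X_k| / n` at frequencies
#' `k fs / n`, k = 1..floor(n/2), so a unit sinusoid at an exact bin has
#' amplitude 1.
#'
#' @param series numeric vector (length >= 8).
#' @param fs series sampling rate in Hz (1/(step x TR)).
#' @return list with `frequency` and `amplitude` vectors.
#' @export
series_spectrum <- function(series, fs) {
  n <- length(series)
  stopifnot(n >= 8, fs > 0)
  X <- stats::fft(series - mean(series))
  half <- n %/% 2L
  list(frequency = (1L:half) * fs / n,
       amplitude = 2 * Mod(X[2L:(half + 1L)]) / n)
}

#' Low-frequency fluctuation amplitude (LFA)
#'
#' Mean one-sided DFT amplitude over bins with `0 < f <= band[2]` Hz
#' (and `f > band[1]`), after mean removal. DC is excluded: a constant
#' offset is not a fluctuation.
#'
#' @param series numeric vector (length >= 8).
#' @param fs series sampling rate in Hz.
#' @param band low-frequency band in Hz, default (0, 0.025].
#' @return non-negative scalar.
#' @export
series_lfa <- function(series, fs, band = c(0, 0.025)) {
  sp <- series_spectrum(series, fs)
  sel <- sp$frequency > band[1] & sp$frequency <= band[2]
  if (!any(sel)) {
    stop("no DFT bin inside (", band[1], ", ", band[2], "] Hz at resolution ",
         fs / length(series), " Hz")
  }
  mean(sp$amplitude[sel])
}

#' KPSS test of level stationarity
#'
#' Null hypothesis: the series is stationary around a constant level. The
#' statistic is `sum_t S_t^2 / (n^2 * s2_l)` with `S_t` the partial sums of
#' the demeaned series and `s2_l` the Bartlett-window long-run variance at
#' lag `l = floor(4 (n/100)^(1/4))`. The p-value is interval-valued against
#' the standard critical-value table (0.347, 0.463, 0.574, 0.739 at 10, 5,
#' 2.5, 1 percent).
#'
#' @param series numeric vector (length >= 20).
#' @param lags Bartlett truncation lag; default the automatic rule above.
#' @return list with `statistic`, `lags`, `p_bound` (string such as
#'   `"< 0.01"` or `"> 0.10"`), and `p_upper` (numeric upper bound, 1 when
#'   above the 10 percent critical value).
#' @export
kpss_stationarity <- function(series, lags = NULL) {
  n <- length(series)
  stopifnot(n >= 20)
  if (is.null(lags)) lags <- floor(4 * (n / 100)^0.25)
  e <- series - mean(series)
  s_t <- cumsum(e)
  s2 <- sum(e^2) / n
  if (lags > 0) {
    for (l in seq_len(lags)) {
      s2 <- s2 + 2 * (1 - l / (lags + 1)) * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  stat <- sum(s_t^2) / (n^2 * s2)
  crit <- c(`0.10` = 0.347, `0.05` = 0.463, `0.025` = 0.574, `0.01` = 0.739)
  above <- stat >= crit
  if (all(above)) {
    p_bound <- "< 0.01"; p_upper <- 0.01
  } else if (!any(above)) {
    p_bound <- "> 0.10"; p_upper <- 1
  } else {
    lev <- names(crit)[max(which(above))]
    p_bound <- paste("<", lev); p_upper <- as.numeric(lev)
  }
  list(statistic = stat, lags = lags, p_bound = p_bound, p_upper = p_upper)
}

#' Dynamic summary of a window series
#'
#' @param series numeric vector of windowed metric values.
#' @param fs series sampling rate in Hz.
#' @param lfa_band low-frequency band in Hz.
#' @return list with `var`, `lfa`, `kpss_stat`, `kpss_p_bound`.
#' @export
dynamic_summary <- function(series, fs, lfa_band = c(0, 0.025)) {
  k <- kpss_stationarity(series)
  list(var = series_variance(series),
       lfa = series_lfa(series, fs, lfa_band),
       kpss_stat = k$statistic, kpss_p_bound = k$p_bound)
}
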