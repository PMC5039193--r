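#' Multi-modal correlation graphs
#'
#' EEG band-power time courses (after HRF convolution) and fMRI IC time
#' courses are concatenated into one joint time x node matrix with the EEG
#' columns first. Its Pearson correlation matrix R (diagonal zeroed) is the
#' weighted graph; to keep both correlation signs, R is split into a
#' non-negative positive-connection graph W+ (positive r kept, else 0) and
#' a non-negative negative-connection graph W- (|r| of negative r kept,
#' else 0). Dynamic graphs repeat this over sliding windows of L TRs in
#' steps of `step` TRs: a T-row matrix yields floor((T - L)/step) + 1
#' windows (237 for T = 256, L = 20, step = 1).
#'
#' @name multimodal_graph
NULL

#' Assemble the joint EEG + fMRI time-course matrix
#'
#' @param eeg_power matrix time x n_eeg (band power on the TR grid,
#'   normally HRF-convolved).
#' @param ic_tc matrix time x n_ics (post-processed IC time courses).
#' @return matrix time x (n_eeg + n_ics), EEG columns first, with
#'   attribute `modality` tagging each column `"EEG"` or `"fMRI"`.
#' @export
build_joint_matrix <- function(eeg_power, ic_tc) {
  eeg_power <- as.matrix(eeg_power); ic_tc <- as.matrix(ic_tc)
  if (nrow(eeg_power) != nrow(ic_tc)) {
    stop("time length mismatch: EEG power has ", nrow(eeg_power),
         " rows, IC time courses have ", nrow(ic_tc))
  }
  if (is.null(colnames(eeg_power))) {
    colnames(eeg_power) <- paste0("EEG", seq_len(ncol(eeg_power)))
  }
  if (is.null(colnames(ic_tc))) {
    colnames(ic_tc) <- paste0("IC", seq_len(ncol(ic_tc)))
  }
  if (length(intersect(colnames(eeg_power), colnames(ic_tc)))) {
    stop("EEG and IC column labels overlap")
  }
  ef <- cbind(eeg_power, ic_tc)
  attr(ef, "modality") <- c(rep("EEG", ncol(eeg_power)),
                            rep("fMRI", ncol(ic_tc)))
  ef
}

#' Pearson correlation graph of a joint matrix
#'
#' Pairwise Pearson correlations between columns; the diagonal is forced to
#' zero so the graph has no self-loops and strength sums exclude
#' self-correlation.
#'
#' @param ef matrix time x N (>= 3 rows; no constant column).
#' @param window label used in the error message for constant columns.
#' @return symmetric N x N matrix, entries in [-1, 1], zero diagonal.
#' @export
correlation_graph <- function(ef, window = "full series") {
  ef <- as.matrix(ef)
  if (nrow(ef) < 3) stop("need >= 3 time points, got ", nrow(ef))
  sds <- apply(ef, 2L, stats::sd)
  if (any(sds == 0)) {
    lab <- colnames(ef)[sds == 0]
    if (is.null(lab)) lab <- which(sds == 0)
    stop("constant column(s) over ", window, ": ", paste(lab, collapse = ", "))
  }
  r <- stats::cor(ef)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]   # exact symmetry
  diag(r) <- 0
  r
}

#' Split a correlation graph into signed non-negative graphs
#'
#' W+ keeps positive correlations (0 elsewhere); W- keeps absolute values
#' of negative correlations (0 elsewhere). Off the diagonal,
#' `w_plus - w_minus` reconstructs R exactly and at most one of the pair is
#' nonzero per edge.
#'
#' @param r correlation graph from [correlation_graph()].
#' @return list of class `signed_graph_pair` with `w_plus` and `w_minus`.
#' @export
split_signed <- function(r) {
  w_plus <- ifelse(r > 0, r, 0)
  w_minus <- ifelse(r < 0, -r, 0)
  dimnames(w_plus) <- dimnames(w_minus) <- dimnames(r)
  structure(list(w_plus = w_plus, w_minus = w_minus),
            class = "signed_graph_pair")
}

#' Sliding-window dynamic graph sequence
#'
#' Window s (0-based start) covers rows [s, s + L); each window yields a
#' correlation graph and its signed split.
#'
#' @param ef joint matrix time x N.
#' @param L window length in TRs (>= 2).
#' @param step window step in TRs (>= 1).
#' @return object of class `dynamic_graph_seq`: list with `starts`
#'   (0-based), `r` (list of window correlation graphs), `signed` (list of
#'   signed pairs), `L`, `step`.
#' @export
sliding_windows <- function(ef, L, step = 1L) {
  ef <- as.matrix(ef)
  T_ <- nrow(ef)
  if (T_ < L) stop("series length T = ", T_, " shorter than window L = ", L)
  stopifnot(L >= 2, step >= 1)
  starts <- seq.int(0L, T_ - L, by = step)
  r <- vector("list", length(starts))
  signed <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    r[[i]] <- correlation_graph(ef[(s + 1L):(s + L), , drop = FALSE],
                                window = paste0("window [", s, ", ", s + L, ")"))
    signed[[i]] <- split_signed(r[[i]])
  }
  structure(list(starts = starts, r = r, signed = signed,
                 L = as.integer(L), step = as.integer(step)),
            class = "dynamic_graph_seq")
}

#' @export
print.dynamic_graph_seq <- function(x, ...) {
  cat("dynamic graph sequence: ", length(x$starts), " windows of L = ",
      x$L, " TRs (step ", x$step, "), ", nrow(x$r[[1]]), " nodes\n", sep = "")
  invisible(x)
}
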