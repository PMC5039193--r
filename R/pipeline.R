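#' End-to-end single-subject graph pipeline
#'
#' Convenience wrapper tying the stages together for one band: EEG ->
#' band-power time courses -> HRF convolution; IC time courses ->
#' post-processing; joint matrix -> static correlation graph and
#' sliding-window dynamic graph sequence.
#'
#' @param eeg matrix channels x samples.
#' @param fs EEG sampling rate in Hz.
#' @param ic_tc matrix time x components (raw; post-processed here unless
#'   `postprocess = FALSE`).
#' @param motion optional time x 6 realignment parameters.
#' @param config [pipeline_config()].
#' @param band band name from `config$bands`.
#' @param hrf_on_eeg_edges when `FALSE`, EEG-EEG edges are recomputed from
#'   unconvolved band power (sensitivity analysis); cross-modal and
#'   fMRI-fMRI edges always use the convolved joint matrix.
#' @param postprocess apply [postprocess_timecourses()] to `ic_tc`.
#' @return list with `ef` (joint matrix), `static` (list `r`, `signed`),
#'   `dynamic` (`dynamic_graph_seq`), `band_power` (unconvolved),
#'   `band_power_hrf` (convolved), `ic_clean`.
#' @export
run_subject_pipeline <- function(eeg, fs, ic_tc, motion = NULL,
                                 config = pipeline_config(),
                                 band = names(config$bands)[1],
                                 hrf_on_eeg_edges = TRUE,
                                 postprocess = TRUE) {
  stopifnot(band %in% names(config$bands))
  n_tr <- nrow(as.matrix(ic_tc))
  bp <- band_power_timecourses(eeg, fs, config, n_epochs = n_tr)[[band]]
  hrf <- canonical_hrf(config$tr_seconds)
  bp_hrf <- convolve_hrf(bp, hrf)
  colnames(bp_hrf) <- colnames(bp)
  ic_clean <- if (postprocess) {
    postprocess_timecourses(ic_tc, motion, config)
  } else as.matrix(ic_tc)
  ef <- build_joint_matrix(bp_hrf, ic_clean)
  patch_eeg <- function(r, rows) {
    n_eeg <- ncol(bp)
    r_eeg <- correlation_graph(bp[rows, , drop = FALSE])
    r[seq_len(n_eeg), seq_len(n_eeg)] <- r_eeg
    r
  }
  r_static <- correlation_graph(ef)
  if (!hrf_on_eeg_edges) r_static <- patch_eeg(r_static, seq_len(n_tr))
  dynamic <- sliding_windows(ef, config$window_length_tr,
                             config$window_step_tr)
  if (!hrf_on_eeg_edges) {
    for (i in seq_along(dynamic$starts)) {
      s <- dynamic$starts[i]
      dynamic$r[[i]] <- patch_eeg(dynamic$r[[i]],
                                  (s + 1L):(s + dynamic$L))
      dynamic$signed[[i]] <- split_signed(dynamic$r[[i]])
    }
  }
  list(ef = ef,
       static = list(r = r_static, signed = split_signed(r_static)),
       dynamic = dynamic,
       band_power = bp, band_power_hrf = bp_hrf, ic_clean = ic_clean)
}
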