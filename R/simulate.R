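#' Seeded synthetic concurrent EEG + IC time courses
#'
#' Generates multichannel EEG and IC time-course matrices with known
#' cross-modal coupling so every pipeline stage has ground truth to
#' recover. EEG channels are sums of band-limited oscillations whose
#' amplitude envelopes follow slow latent signals; coupled IC columns carry
#' the same latent envelope after convolution with the canonical HRF, plus
#' noise scaled so the realized EEG-power/IC correlation approaches a
#' target; uncoupled ICs are band-pass filtered noise. Coupling patterns
#' can switch on a TR schedule (planted connectivity states) and coupling
#' strengths can be boosted at chosen IC nodes in one condition (planted
#' eyes-open/eyes-closed effects).
#'
#' @name synthetic_data
NULL

#' Simulation specification
#'
#' @param n_subjects number of subjects per condition.
#' @param n_time_tr TRs per run.
#' @param tr_seconds TR in seconds.
#' @param eeg_fs EEG sampling rate in Hz (250 by default: desk-scale).
#' @param n_channels EEG channels.
#' @param n_ics IC time courses.
#' @param couplings data.frame with columns `channel`, `band`, `ic`,
#'   `strength` (target correlation in (-1, 1)) and `pattern` (which
#'   schedule pattern activates the coupling). Default: six alpha-band
#'   couplings of channels 1-6 to ICs 1-6 at strength 0.5.
#' @param state_schedule 2-column matrix (start_tr, pattern_id); must start
#'   at TR 0 with strictly increasing starts inside [0, n_time_tr).
#' @param condition_effect `NULL`, or list with `ic_nodes` (integer IC
#'   indices) and `boost` (added to the strengths of couplings into those
#'   ICs during the eyes-closed condition).
#' @param noise_sd additive EEG noise SD and IC noise scale (on unit-power
#'   oscillations); at `noise_sd = 1` the realized latent/IC correlation
#'   matches `strength`.
#' @param envelope_gain modulation depth of band-power envelopes.
#' @param rng_seed base seed; each subject x condition derives its own
#'   sub-seed from it.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 25, n_time_tr = 256, tr_seconds = 2,
                            eeg_fs = 250, n_channels = 30, n_ics = 54,
                            couplings = data.frame(
                              channel = seq_len(min(6, n_channels, n_ics)),
                              band = "alpha",
                              ic = seq_len(min(6, n_channels, n_ics)),
                              strength = 0.5, pattern = 1L),
                            state_schedule = cbind(0L, 1L),
                            condition_effect = NULL,
                            noise_sd = 1, envelope_gain = 0.8,
                            rng_seed = 1L) {
  stopifnot(n_subjects >= 1, tr_seconds > 0, eeg_fs > 0,
            n_channels >= 1, n_ics >= 1, noise_sd >= 0)
  if (n_time_tr * tr_seconds < 24) {
    stop("run too short: n_time_tr x tr_seconds must cover at least one ",
         "hemodynamic response (24 s)")
  }
  state_schedule <- matrix(as.integer(state_schedule), ncol = 2)
  if (state_schedule[1, 1] != 0 ||
      any(diff(state_schedule[, 1]) <= 0) ||
      any(state_schedule[, 1] >= n_time_tr)) {
    stop("state_schedule must start at TR 0 with strictly increasing ",
         "starts inside [0, n_time_tr)")
  }
  stopifnot(all(abs(couplings$strength) < 1), all(couplings$strength != 0),
            all(couplings$channel >= 1), all(couplings$channel <= n_channels),
            all(couplings$ic >= 1), all(couplings$ic <= n_ics))
  r_max <- 1 / sqrt(1 + noise_sd^2)
  if (any(abs(couplings$strength) > r_max)) {
    stop("coupling target |r| exceeds the attainable bound ",
         sprintf("%.3f", r_max), " at noise_sd = ", noise_sd)
  }
  structure(list(n_subjects = n_subjects, n_time_tr = as.integer(n_time_tr),
                 tr_seconds = tr_seconds, eeg_fs = eeg_fs,
                 n_channels = as.integer(n_channels),
                 n_ics = as.integer(n_ics), couplings = couplings,
                 state_schedule = state_schedule,
                 condition_effect = condition_effect,
                 noise_sd = noise_sd, envelope_gain = envelope_gain,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_spec")
}

# slow latent signal on the TR grid: low-pass filtered Gaussian noise
# (cutoff 0.05 Hz) so the fMRI band-pass (0.01-0.10 Hz) preserves it
.slow_envelope <- function(n_tr, tr_seconds) {
  fs <- 1 / tr_seconds
  bf <- signal::butter(2, min(0.05 / (fs / 2), 0.9), type = "low")
  e <- signal::filtfilt(bf, stats::rnorm(n_tr))
  as.numeric(scale(e))
}

.band_center <- function(band_name, bands) {
  b <- bands[[band_name]]
  if (is.null(b)) stop("unknown band in couplings: ", band_name)
  mean(b)
}

.pattern_per_tr <- function(schedule, n_tr) {
  pat <- integer(n_tr)
  for (i in seq_len(nrow(schedule))) {
    from <- schedule[i, 1] + 1L
    to <- if (i < nrow(schedule)) schedule[i + 1, 1] else n_tr
    pat[from:to] <- schedule[i, 2]
  }
  pat
}

.subject_seed <- function(spec, subject_index, condition) {
  # double arithmetic: exact below 2^53, avoids 32-bit integer overflow
  s <- (as.numeric(spec$rng_seed) * 100003 + subject_index * 131 +
          if (condition == "EC") 31 else 0) %% 2147483647
  as.integer(s)
}

#' Simulate one subject run
#'
#' @param spec [simulation_spec()].
#' @param subject_index subject number (1-based).
#' @param condition `"EO"` or `"EC"`; with a `condition_effect` in the
#'   spec, couplings into the designated ICs are boosted during `"EC"`.
#' @param config [pipeline_config()] supplying the band definitions.
#' @return list with `eeg` (channels x samples, `meta$sampling_rate` set),
#'   `ic_tc` (time x n_ics), `motion` (time x 6), and `truth` (envelopes,
#'   per-TR pattern, effective couplings, seed).
#' @export
simulate_subject <- function(spec, subject_index = 1L,
                             condition = c("EO", "EC"),
                             config = pipeline_config()) {
  condition <- match.arg(condition)
  stopifnot(inherits(spec, "simulation_spec"))
  seed <- .subject_seed(spec, subject_index, condition)
  set.seed(seed)
  n_tr <- spec$n_time_tr
  spe <- as.integer(round(spec$eeg_fs * spec$tr_seconds))
  n_samp <- n_tr * spe
  cpl <- spec$couplings
  if (condition == "EC" && !is.null(spec$condition_effect)) {
    hit <- cpl$ic %in% spec$condition_effect$ic_nodes
    cpl$strength[hit] <- sign(cpl$strength[hit]) *
      pmin(0.95, abs(cpl$strength[hit]) + spec$condition_effect$boost)
  }
  patterns <- sort(unique(cpl$pattern))
  env <- vapply(patterns, function(p) .slow_envelope(n_tr, spec$tr_seconds),
                numeric(n_tr))
  colnames(env) <- paste0("pattern", patterns)
  pat_tr <- .pattern_per_tr(spec$state_schedule, n_tr)
  hrf <- canonical_hrf(spec$tr_seconds,
                       max(24, min(32, n_tr * spec$tr_seconds)))
  t_sec <- (seq_len(n_samp) - 1) / spec$eeg_fs
  tr_of_sample <- rep(seq_len(n_tr), each = spe)

  # EEG: per channel, one oscillation per band, amplitude-modulated where
  # a coupling into the active pattern exists
  eeg <- matrix(0, nrow = spec$n_channels, ncol = n_samp,
                dimnames = list(sprintf("CH%02d", seq_len(spec$n_channels)),
                                NULL))
  for (ch in seq_len(spec$n_channels)) {
    x <- numeric(n_samp)
    for (bn in names(config$bands)) {
      amp_tr <- rep(1, n_tr)
      rows <- which(cpl$channel == ch & cpl$band == bn)
      for (ri in rows) {
        active <- pat_tr == cpl$pattern[ri]
        amp_tr[active] <- sqrt(pmax(
          0.05, 1 + spec$envelope_gain * env[active, paste0("pattern", cpl$pattern[ri])]))
      }
      f0 <- .band_center(bn, config$bands)
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + amp_tr[tr_of_sample] * sin(2 * pi * f0 * t_sec + phase)
    }
    eeg[ch, ] <- x + spec$noise_sd * stats::rnorm(n_samp)
  }
  attr(eeg, "meta") <- list(sampling_rate = spec$eeg_fs)

  # ICs: coupled columns carry the HRF-lagged envelope of their pattern
  # while that pattern is active; the rest is filtered noise
  ic <- matrix(0, nrow = n_tr, ncol = spec$n_ics,
               dimnames = list(NULL, sprintf("IC%02d", seq_len(spec$n_ics))))
  filt_noise <- function() {
    as.numeric(scale(bandpass(stats::rnorm(n_tr), config$bandpass_hz[1],
                              config$bandpass_hz[2], spec$tr_seconds)))
  }
  z_env <- apply(env, 2L, function(e) {
    as.numeric(scale(convolve_hrf(e, hrf)))
  })
  for (j in seq_len(spec$n_ics)) {
    rows <- which(cpl$ic == j)
    if (!length(rows)) {
      ic[, j] <- filt_noise()
      next
    }
    sig <- numeric(n_tr)
    noise_scale <- 0
    for (ri in rows) {
      active <- pat_tr == cpl$pattern[ri]
      r_t <- cpl$strength[ri]
      sig[active] <- sig[active] +
        sign(r_t) * z_env[active, paste0("pattern", cpl$pattern[ri])]
      noise_scale <- max(noise_scale,
                         spec$noise_sd * sqrt(1 / r_t^2 - 1))
    }
    ic[, j] <- sig + noise_scale * filt_noise()
  }

  motion <- apply(matrix(stats::rnorm(n_tr * 6, sd = 0.02), ncol = 6), 2L,
                  cumsum)
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  list(eeg = eeg, ic_tc = ic, motion = motion,
       truth = list(envelopes = env, pattern_per_tr = pat_tr,
                    couplings = cpl, seed = seed, condition = condition))
}

#' Simulate and write a full cohort
#'
#' One directory per subject and condition, each holding `eeg.tsv`
#' (sample-major), `ic.tsv`, `motion.tsv`; a `truth.yaml` manifest at the
#' root records every planted parameter.
#'
#' @param spec [simulation_spec()].
#' @param dir output directory (created; must be empty unless `force`).
#' @param config [pipeline_config()].
#' @param write_edf_files also write `eeg.edf` next to each `eeg.tsv`.
#' @param force overwrite a non-empty directory.
#' @return `dir`, invisibly.
#' @export
simulate_cohort <- function(spec, dir, config = pipeline_config(),
                            write_edf_files = FALSE, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop("output directory '", dir, "' exists and is non-empty; ",
         "use force = TRUE to overwrite")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_len(spec$n_subjects)) {
    for (cond in c("EO", "EC")) {
      sub <- simulate_subject(spec, s, cond, config)
      d <- file.path(dir, sprintf("sub-%02d", s), cond)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_labeled_matrix(t(sub$eeg), file.path(d, "eeg.tsv"),
                           meta = list(sampling_rate = spec$eeg_fs))
      if (write_edf_files) {
        write_edf(sub$eeg, file.path(d, "eeg.edf"), spec$eeg_fs)
      }
      write_labeled_matrix(sub$ic_tc, file.path(d, "ic.tsv"),
                           meta = list(tr_seconds = spec$tr_seconds))
      write_labeled_matrix(sub$motion, file.path(d, "motion.tsv"))
    }
  }
  truth <- list(
    n_subjects = spec$n_subjects, n_time_tr = spec$n_time_tr,
    tr_seconds = spec$tr_seconds, eeg_fs = spec$eeg_fs,
    n_channels = spec$n_channels, n_ics = spec$n_ics,
    couplings = as.list(spec$couplings),
    state_schedule = apply(spec$state_schedule, 1L, as.list),
    condition_effect = spec$condition_effect,
    noise_sd = spec$noise_sd, rng_seed = spec$rng_seed)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Specification with two alternating planted connectivity states
#'
#' Canonical two-regime experiment: the schedule alternates two coupling
#' patterns every `block_tr` TRs; pattern 1 couples channels 1-10 (alpha)
#' to ICs 1-10, pattern 2 couples the same channels to ICs 11-20, both at
#' strength 0.7 with `noise_sd = 0.5`, so each regime plants one strongly
#' intercorrelated 20-node cluster and the window strength profiles of the
#' two regimes are clearly distinct.
#'
#' @param rng_seed base seed.
#' @param block_tr regime block length in TRs.
#' @param n_time_tr run length in TRs.
#' @param strength coupling target correlation.
#' @param noise_sd noise level (see [simulation_spec()]).
#' @return `simulation_spec` object.
#' @export
two_state_spec <- function(rng_seed = 1L, block_tr = 60L, n_time_tr = 256L,
                           strength = 0.7, noise_sd = 0.5) {
  starts <- seq.int(0L, n_time_tr - 1L, by = block_tr)
  schedule <- cbind(starts, rep_len(c(1L, 2L), length(starts)))
  simulation_spec(
    n_subjects = 1, n_time_tr = n_time_tr, noise_sd = noise_sd,
    couplings = data.frame(channel = rep(1:10, 2), band = "alpha",
                           ic = c(1:10, 11:20), strength = strength,
                           pattern = rep(1:2, each = 10)),
    state_schedule = schedule, rng_seed = rng_seed)
}

#' Run the planted-state recovery experiment for one seed
#'
#' Simulates one subject from `spec`, runs the full pipeline (band power,
#' HRF, post-processing, joint matrix, sliding windows), detects
#' connectivity states from the CCS matrix, and scores the partition
#' against the planted schedule. Windows straddling a regime switch
#' (mixed-pattern windows) are excluded from the agreement score;
#' agreement is the best state-to-pattern mapping when K matches the
#' planted regime count, else the purity of the partition.
#'
#' @param spec `simulation_spec` with a multi-pattern schedule (e.g.
#'   [two_state_spec()]).
#' @param config [pipeline_config()].
#' @param band band used for the graph.
#' @param sign connection sign for the strength profiles.
#' @return list with `K`, `agreement`, `partition`, `n_scored`.
#' @export
planted_state_recovery <- function(spec, config = pipeline_config(),
                                   band = "alpha", sign = "positive") {
  sub <- simulate_subject(spec, 1L, "EO", config)
  pl <- run_subject_pipeline(sub$eeg, spec$eeg_fs, sub$ic_tc, sub$motion,
                             config, band = band)
  part <- detect_states(ccs_matrix(strength_profiles(pl$dynamic, sign)))
  pat <- sub$truth$pattern_per_tr
  L <- pl$dynamic$L
  win_pat <- vapply(pl$dynamic$starts, function(s) {
    p <- unique(pat[(s + 1L):(s + L)])
    if (length(p) == 1L) p else NA_integer_
  }, integer(1))
  keep <- !is.na(win_pat)
  tab <- table(factor(win_pat[keep]), factor(part$assignment[keep]))
  agreement <- if (nrow(tab) == ncol(tab)) {
    perms <- .permutations(ncol(tab))
    max(vapply(perms, function(p) {
      sum(tab[cbind(seq_len(nrow(tab)), p)])
    }, numeric(1))) / sum(tab)
  } else {
    sum(apply(tab, 1L, max)) / sum(tab)   # purity when K != planted count
  }
  list(K = part$K, agreement = agreement, partition = part,
       n_scored = sum(keep))
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Simulate per-subject measure tables for group statistics
#'
#' Reduced-scale cohort generator at the level the group tests consume: one
#' subjects x bands x conditions array per node, with subject and band
#' main effects, compound-symmetric unit within-cell noise, and an
#' additive condition shift (in within-cell SD units) planted at
#' `effect_nodes` in condition 2.
#'
#' @param n_subjects,n_nodes,n_bands design size.
#' @param effect_nodes integer indices of nodes carrying the planted
#'   effect.
#' @param effect_sd shift magnitude in within-cell SD units.
#' @param subject_sd,band_sd SDs of the subject and band random effects.
#' @return named list of `n_nodes` arrays (subjects x bands x 2).
#' @export
simulate_measure_tables <- function(n_subjects = 25, n_nodes = 54,
                                    n_bands = 5, effect_nodes = integer(),
                                    effect_sd = 1, subject_sd = 1,
                                    band_sd = 0.5) {
  out <- vector("list", n_nodes)
  names(out) <- sprintf("IC%02d", seq_len(n_nodes))
  subj <- stats::rnorm(n_subjects, sd = subject_sd)
  for (nd in seq_len(n_nodes)) {
    band_mu <- stats::rnorm(n_bands, sd = band_sd)
    tab <- array(stats::rnorm(n_subjects * n_bands * 2),
                 dim = c(n_subjects, n_bands, 2))
    tab <- tab + subj                      # recycles over subject axis
    tab <- tab + rep(band_mu, each = n_subjects)
    if (nd %in% effect_nodes) tab[, , 2] <- tab[, , 2] + effect_sd
    out[[nd]] <- tab
  }
  out
}
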