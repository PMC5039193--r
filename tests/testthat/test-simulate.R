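small_spec <- function(...) {
  simulation_spec(n_subjects = 1, n_time_tr = 64, eeg_fs = 100,
                  n_channels = 4, n_ics = 6,
                  couplings = data.frame(channel = 1, band = "alpha",
                                         ic = 1, strength = 0.5,
                                         pattern = 1L), ...)
}

test_that("the same seed reproduces a subject exactly", {
  spec <- small_spec(rng_seed = 91)
  a <- simulate_subject(spec, 1, "EO")
  b <- simulate_subject(spec, 1, "EO")
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$ic_tc, b$ic_tc)
  expect_identical(a$motion, b$motion)
  # different subject or condition changes the data
  c_ <- simulate_subject(spec, 2, "EO")
  d <- simulate_subject(spec, 1, "EC")
  expect_false(identical(a$eeg, c_$eeg))
  expect_false(identical(a$eeg, d$eeg))
})

test_that("spec validation catches impossible targets and bad schedules", {
  expect_error(simulation_spec(couplings = data.frame(
    channel = 1, band = "alpha", ic = 1, strength = 0.9, pattern = 1L),
    noise_sd = 1), "attainable bound")
  expect_error(small_spec(state_schedule = rbind(c(5, 1))), "start at TR 0")
  expect_error(small_spec(state_schedule = rbind(c(0, 1), c(0, 2))),
               "increasing")
  expect_error(small_spec(state_schedule = rbind(c(0, 1), c(64, 2))),
               "n_time_tr")
})

test_that("noiseless coupling yields near-perfect realized correlation", {
  spec <- simulation_spec(n_subjects = 1, n_time_tr = 256, eeg_fs = 100,
                          n_channels = 2, n_ics = 2,
                          couplings = data.frame(channel = 1, band = "alpha",
                                                 ic = 1, strength = 0.6,
                                                 pattern = 1L),
                          noise_sd = 0, rng_seed = 92)
  sub <- simulate_subject(spec, 1, "EO")
  bp <- band_power_timecourses(sub$eeg, 100, pipeline_config(),
                               n_epochs = 256)$alpha
  conv <- convolve_hrf(bp[, 1], canonical_hrf(2))
  expect_gte(abs(cor(conv, sub$ic_tc[, 1])), 0.95)
})

test_that("planted coupling is realized well above the noise floor", {
  hits <- 0
  for (seed in 1:20) {
    spec <- simulation_spec(n_subjects = 1, n_time_tr = 256, eeg_fs = 100,
                            n_channels = 12, n_ics = 6,
                            couplings = data.frame(channel = 10,
                                                   band = "alpha", ic = 3,
                                                   strength = 0.6,
                                                   pattern = 1L),
                            noise_sd = 1, rng_seed = seed)
    sub <- simulate_subject(spec, 1, "EO")
    bp <- band_power_timecourses(sub$eeg, 100, pipeline_config(),
                                 n_epochs = 256)$alpha
    conv <- convolve_hrf(bp[, 10], canonical_hrf(2))
    if (abs(cor(conv, sub$ic_tc[, 3])) >= 0.4) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("zero coupling gives edge correlations near the 1/sqrt(L) law", {
  spec <- simulation_spec(n_subjects = 1, n_time_tr = 256, eeg_fs = 100,
                          n_channels = 6, n_ics = 10,
                          couplings = data.frame(channel = 1, band = "alpha",
                                                 ic = 1, strength = 1e-3,
                                                 pattern = 1L),
                          noise_sd = 1, rng_seed = 93)
  sub <- simulate_subject(spec, 1, "EO")
  cfg <- pipeline_config()
  pl <- run_subject_pipeline(sub$eeg, 100, sub$ic_tc, sub$motion, cfg,
                             band = "theta")   # theta carries no coupling
  L <- cfg$window_length_tr
  cross <- unlist(lapply(pl$dynamic$r, function(r) r[1:6, 7:16]))
  expect_lt(abs(mean(cross)), 0.1)
  # band-passed series are autocorrelated, so the effective number of
  # independent samples per window is below L; accept a generous band
  expect_gt(sd(cross), 0.8 / sqrt(L))
  expect_lt(sd(cross), 3 / sqrt(L))
})

test_that("stronger planted coupling raises the realized edge weight", {
  med <- vapply(c(0.2, 0.45, 0.7), function(s) {
    r <- vapply(1:5, function(seed) {
      spec <- simulation_spec(n_subjects = 1, n_time_tr = 128, eeg_fs = 100,
                              n_channels = 2, n_ics = 2,
                              couplings = data.frame(channel = 1,
                                                     band = "alpha", ic = 1,
                                                     strength = s,
                                                     pattern = 1L),
                              noise_sd = 0.7, rng_seed = seed)
      sub <- simulate_subject(spec, 1, "EO")
      bp <- band_power_timecourses(sub$eeg, 100, pipeline_config(),
                                   n_epochs = 128)$alpha
      cor(convolve_hrf(bp[, 1], canonical_hrf(2)), sub$ic_tc[, 1])
    }, numeric(1))
    median(r)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("cohort writer produces a parseable tree and refuses overwrite", {
  d <- withr::local_tempdir()
  spec <- simulation_spec(n_subjects = 2, n_time_tr = 16, eeg_fs = 50,
                          n_channels = 3, n_ics = 4,
                          couplings = data.frame(channel = 1, band = "alpha",
                                                 ic = 1, strength = 0.5,
                                                 pattern = 1L), rng_seed = 94)
  out <- file.path(d, "cohort")
  simulate_cohort(spec, out)
  for (s in c("sub-01", "sub-02")) for (cond in c("EO", "EC")) {
    eeg <- read_eeg(file.path(out, s, cond, "eeg.tsv"))
    expect_equal(dim(eeg), c(3, 16 * 50 * 2))
    ic <- read_timecourses(file.path(out, s, cond, "ic.tsv"))
    expect_equal(dim(ic), c(16, 4))
    expect_equal(dim(read_labeled_matrix(file.path(out, s, cond, "motion.tsv"))),
                 c(16, 6))
  }
  truth <- yaml::read_yaml(file.path(out, "truth.yaml"))
  expect_equal(truth$n_subjects, 2)
  expect_error(simulate_cohort(spec, out), "non-empty")
  expect_silent(simulate_cohort(spec, out, force = TRUE))
})

test_that("a planted EC>EO boost shifts realized coupling by condition", {
  spec <- simulation_spec(n_subjects = 1, n_time_tr = 128, eeg_fs = 100,
                          n_channels = 2, n_ics = 3,
                          couplings = data.frame(channel = 1, band = "alpha",
                                                 ic = 1, strength = 0.3,
                                                 pattern = 1L),
                          condition_effect = list(ic_nodes = 1, boost = 0.3),
                          noise_sd = 0.7, rng_seed = 95)
  r_of <- function(cond) {
    mean(vapply(1:6, function(s) {
      sub <- simulate_subject(spec, s, cond)
      bp <- band_power_timecourses(sub$eeg, 100, pipeline_config(),
                                   n_epochs = 128)$alpha
      cor(convolve_hrf(bp[, 1], canonical_hrf(2)), sub$ic_tc[, 1])
    }, numeric(1)))
  }
  expect_gt(r_of("EC"), r_of("EO"))
})
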