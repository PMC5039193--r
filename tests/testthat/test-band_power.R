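test_that("variance normalization gives zero-mean unit-variance channels", {
  x <- matrix(c(1, 3), 1, 2)
  z <- variance_normalize(x)
  expect_equal(as.vector(z), c(-1, 1) / sqrt(2))  # n-1 divisor two-point case
  set.seed(21)
  y <- matrix(rnorm(3 * 500), 3)
  zy <- variance_normalize(y)
  expect_equal(rowMeans(zy), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(zy, 1, var), rep(1, 3), tolerance = 1e-12)
  # already standardized noise is unchanged
  expect_equal(variance_normalize(zy), zy, tolerance = 1e-10)
  y[2, ] <- 7
  rownames(y) <- c("Fz", "Cz", "Pz")
  expect_error(variance_normalize(y), "Cz")
})

test_that("epoching is consecutive, TR-aligned, and counts epochs correctly", {
  fs <- 100
  x <- matrix(seq_len(2 * 512 * fs), nrow = 2, byrow = TRUE)
  ep <- segment_epochs(x, fs, 2)               # 512 s -> 256 epochs
  expect_equal(dim(ep), c(256, 2, 200))
  # epoch k covers samples [k*fs*2, (k+1)*fs*2), half-open, 0-based
  expect_equal(ep[1, 1, ], as.numeric(1:200))
  expect_equal(ep[3, 1, ], as.numeric(401:600))
  ep2 <- segment_epochs(matrix(rnorm(2 * 400), 2), 100, 2)
  expect_equal(dim(ep2)[1], 2)
  expect_error(segment_epochs(matrix(rnorm(2 * 390), 2), 100, 2, n_epochs = 2),
               "available")
})

test_that("band power concentrates at the oscillation frequency", {
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  cfg <- pipeline_config()
  x <- matrix(sin(2 * pi * 10 * t), 1)         # pure 10 Hz, alpha band
  ep <- segment_epochs(x, fs, 2)
  bands <- cfg$bands
  p <- vapply(seq_along(bands), function(i) {
    b <- bands[[i]]
    epoch_band_power(ep, fs, b[1], b[2], closed_top = i == length(bands))[1, 1]
  }, numeric(1))
  names(p) <- names(bands)
  expect_gt(p["alpha"], 100 * max(p[names(p) != "alpha"]))
  # all-zero epoch has zero power everywhere
  ep0 <- segment_epochs(matrix(0, 1, 2000), fs, 2)
  expect_equal(epoch_band_power(ep0, fs, 8, 13)[1, 1], 0)
})

test_that("equal-amplitude tones at bin centers give equal band powers", {
  # closed-form DFT: a unit sinusoid at an exact bin puts all its power in
  # that bin, so theta (5 Hz) and beta (20 Hz) see one bin each with equal
  # magnitude; per-band averages differ only by bin count
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- matrix(sin(2 * pi * 5 * t) + sin(2 * pi * 20 * t), 1)
  ep <- segment_epochs(x, fs, 2)
  n_bins <- function(lo, hi) sum((1:1000) * fs / 2000 >= lo &
                                   (1:1000) * fs / 2000 < hi)
  theta <- epoch_band_power(ep, fs, 4, 8)[1, 1] * n_bins(4, 8)
  beta <- epoch_band_power(ep, fs, 13, 30)[1, 1] * n_bins(13, 30)
  expect_equal(theta, beta, tolerance = 0.01)
  delta <- epoch_band_power(ep, fs, 1, 4)[1, 1]
  gamma <- epoch_band_power(ep, fs, 30, 35, closed_top = TRUE)[1, 1]
  expect_lt(delta, 1e-6 * theta)
  expect_lt(gamma, 1e-6 * theta)
})

test_that("a band narrower than the bin resolution is rejected", {
  ep <- segment_epochs(matrix(rnorm(40), 1), 10, 2)  # 0.5 Hz resolution
  expect_error(epoch_band_power(ep, 10, 1.1, 1.3), "resolution")
})

test_that("band powers are invariant to circular shifts of an epoch", {
  set.seed(22)
  x <- matrix(rnorm(200), 1)
  xs <- matrix(x[1, c(51:200, 1:50)], 1)
  ep <- segment_epochs(x, 100, 2)
  eps <- segment_epochs(xs, 100, 2)
  expect_equal(epoch_band_power(ep, 100, 8, 13),
               epoch_band_power(eps, 100, 8, 13), tolerance = 1e-10)
})

test_that("band powers over a bin partition sum to total non-DC power", {
  set.seed(23)
  fs <- 100
  x <- matrix(rnorm(3 * 400), 3)
  ep <- segment_epochs(x, fs, 2)
  edges <- c(0.5, 10, 22.5, 37, 50)
  n <- 200
  freq <- (1:(n / 2)) * fs / n
  total <- 0
  for (i in seq_len(length(edges) - 1)) {
    nb <- sum(if (i == length(edges) - 1) freq >= edges[i] & freq <= edges[i + 1]
              else freq >= edges[i] & freq < edges[i + 1])
    total <- total + nb * epoch_band_power(ep, fs, edges[i], edges[i + 1],
                                           closed_top = i == length(edges) - 1)
  }
  # Parseval restricted to covered bins: compare to direct spectrum sum
  flat <- matrix(aperm(ep, c(3, 1, 2)), nrow = n)
  ref <- colSums(2 * Mod(stats::mvfft(flat)[2:(n / 2 + 1), ])^2 / n^2)
  covered <- freq >= edges[1]
  expect_equal(as.vector(total), ref, tolerance = 1e-9)
})

test_that("canonical HRF has the right peak, undershoot, and sampling", {
  h <- canonical_hrf(2, 32)
  expect_length(h, 16)
  # peak-normalized against the continuous kernel: grid maximum just below 1
  expect_lte(max(h), 1)
  expect_gt(max(h), 0.9)   # TR grid straddles the continuous peak (~5.2 s)
  expect_equal(max(canonical_hrf(0.01, 32)), 1, tolerance = 1e-4)
  expect_true(which.max(h) %in% c(3, 4))        # peak near 5-6 s (0-based 2-3)
  expect_gt(which.min(h), which.max(h))         # undershoot after the peak
  expect_lt(min(h), 0)
  h1 <- canonical_hrf(1, 32)
  expect_equal(h1[seq(1, 31, by = 2)], as.numeric(canonical_hrf(2, 32)),
               tolerance = 1e-12)
})

test_that("HRF convolution is causal, linear, and delays the input", {
  h <- canonical_hrf(2, 32)
  imp <- c(1, rep(0, 49))
  out <- convolve_hrf(imp, h)
  expect_equal(out[1:16], as.numeric(h), tolerance = 1e-12)
  expect_equal(out[17:50], rep(0, 34), tolerance = 1e-12)
  ones <- convolve_hrf(rep(1, 100), h)
  expect_equal(ones[100], sum(h), tolerance = 1e-10)
  set.seed(24)
  x <- rnorm(64); y <- rnorm(64)
  expect_equal(convolve_hrf(2 * x - 3 * y, h),
               2 * convolve_hrf(x, h) - 3 * convolve_hrf(y, h),
               tolerance = 1e-10)
  expect_error(convolve_hrf(rnorm(10), h), "exceeds")
  # white noise correlates with its convolution most strongly at the
  # kernel's peak lag, not at lag 0
  set.seed(25)
  w <- rnorm(256)
  cw <- convolve_hrf(w, h)
  lag <- which.max(h) - 1
  r0 <- cor(w, cw)
  rpk <- cor(w[1:(256 - lag)], cw[(1 + lag):256])
  expect_gt(rpk, r0)
})

test_that("band_power_timecourses produces one TR-resolution matrix per band", {
  set.seed(26)
  fs <- 100
  eeg <- matrix(rnorm(4 * fs * 2 * 12), 4,
                dimnames = list(paste0("CH", 1:4), NULL))
  bp <- band_power_timecourses(eeg, fs, pipeline_config(), n_epochs = 10)
  expect_named(bp, c("delta", "theta", "alpha", "beta", "low_gamma"))
  for (m in bp) {
    expect_equal(dim(m), c(10, 4))
    expect_true(all(m >= 0))
  }
  # matches the standalone per-band operation
  ep <- segment_epochs(variance_normalize(eeg), fs, 2, 10)
  expect_equal(bp$alpha, epoch_band_power(ep, fs, 8, 13), tolerance = 1e-12)
  expect_equal(bp$low_gamma, epoch_band_power(ep, fs, 30, 35, closed_top = TRUE),
               tolerance = 1e-12)
})
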