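test_that("low-pass filter has unity DC gain and the analytic stop-band attenuation", {
  x <- rep(3.7, 4000)
  y <- butter_lowpass(x, fs_std, filter_spec(3, 8))
  core <- 500:3500
  expect_lt(max(abs(y[core] - 3.7)), 1e-6)

  # |H(f)| = 1 / sqrt(1 + (f/fc)^(2n)) for a Butterworth low-pass
  r50 <- tone_ratio(50, fs_std, 6, function(x)
    butter_lowpass(x, fs_std, filter_spec(3, 8, zero_phase = FALSE)))
  expect_lt(abs(r50 / 0.004096 - 1), 0.15)
  r50zp <- tone_ratio(50, fs_std, 6, function(x)
    butter_lowpass(x, fs_std, filter_spec(3, 8, zero_phase = TRUE)))
  expect_lt(abs(r50zp / 0.004096^2 - 1), 0.3)
  r1 <- tone_ratio(1, fs_std, 6, function(x)
    butter_lowpass(x, fs_std, filter_spec(3, 8, zero_phase = FALSE)))
  expect_gt(r1, 0.99)
})

test_that("filters preserve length, reject invalid cutoffs, and zero-phase is time-symmetric", {
  x <- rnorm(3000)
  y <- butter_lowpass(x, fs_std, filter_spec(3, 8))
  expect_length(y, length(x))
  expect_error(butter_lowpass(x, 100, filter_spec(3, 60)),
               class = "pf_invalid_filter")
  # filtering the reversed signal and reversing equals filtering the
  # signal (away from the padded edges, where the startup transients of
  # the two directions differ at round-off scale)
  y_rev <- rev(butter_lowpass(rev(x), fs_std, filter_spec(3, 8)))
  core <- 501:2500
  expect_equal(y[core], y_rev[core], tolerance = 1e-8)
})

test_that("attenuation is monotone in frequency above the cutoff", {
  freqs <- c(10, 15, 20, 30, 40, 60)
  ratios <- vapply(freqs, function(f)
    tone_ratio(f, fs_std, 4, function(x) butter_lowpass(x, fs_std, filter_spec(3, 8))),
    numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("spline baseline removal interpolates exactly and recovers injected drift", {
  # a signal already zero at its anchors and baseline-free passes through
  fs <- fs_std
  t <- (0:(6 * fs - 1)) / fs
  clean <- abs(sin(pi * t / 0.75))          # arches, zero every 0.75 s
  anchors <- round(seq(0, 5.25, by = 0.75) * fs) + 1L
  out <- spline_baseline_remove(clean, anchors)
  expect_lt(max(abs(out$corrected - clean)), 1e-9)

  # injected respiratory drift is mostly removed
  A <- 0.5
  drift <- A * sin(2 * pi * 0.25 * t)
  out2 <- spline_baseline_remove(clean + drift, anchors)
  core <- (fs + 1):(5 * fs)
  rms_resid <- sqrt(mean((out2$corrected[core] - clean[core])^2))
  expect_lt(rms_resid, 0.1 * A)
  # corrected is exactly zero at every anchor, whatever the input
  x <- rnorm(2000)
  a2 <- c(100L, 500L, 900L, 1500L)
  expect_equal(spline_baseline_remove(x, a2)$corrected[a2], rep(0, 4))
})

test_that("spline baseline removal needs at least four anchors", {
  expect_error(spline_baseline_remove(rnorm(100), c(10L, 50L, 90L)),
               class = "pf_insufficient_anchors")
})

test_that("two-stage ECG filtering separates the 50 Hz, 30 Hz and DC components", {
  r50 <- tone_ratio(50, fs_std, 6, function(x) ecg_two_stage(x, fs_std)$stage1)
  expect_lt(r50^2, 0.10)                   # power reduced below 10%
  r30a <- tone_ratio(30, fs_std, 6, function(x) ecg_two_stage(x, fs_std)$stage1)
  r30b <- tone_ratio(30, fs_std, 6, function(x) ecg_two_stage(x, fs_std)$stage2)
  expect_gt(r30a, 0.5)
  expect_lt(r30b, 0.2)
  x <- rep(0.42, 5000)
  st <- ecg_two_stage(x, fs_std)
  core <- 1000:4000
  expect_lt(max(abs(st$stage1[core] - 0.42)), 1e-6)
  expect_lt(max(abs(st$stage2[core] - 0.42)), 1e-6)
})

test_that("ECG baseline removal is an exact additive decomposition within the allowed band", {
  # a drift-free input: a beat train with its own sub-0.5 Hz content removed
  x0 <- make_ecg_train(rep(0.8, 10))
  x <- ecg_baseline_remove(x0, fs_std, fc = 0.5)$corrected
  out <- ecg_baseline_remove(x, fs_std, fc = 0.5)
  expect_equal(out$corrected + out$baseline, x, tolerance = 1e-6)
  expect_error(ecg_baseline_remove(x, fs_std, fc = 0.7), class = "pf_invalid_filter")
  expect_silent(ecg_baseline_remove(x, fs_std, fc = 0.7, override = TRUE))

  # drift-free ECG passes nearly unchanged
  core <- (2 * fs_std):(length(x) - 2 * fs_std)
  expect_lt(sqrt(mean((out$corrected[core] - x[core])^2)),
            0.02 * sqrt(mean(x[core]^2)))

  # an injected 0.3 Hz drift is strongly attenuated
  A <- 0.4
  drift <- A * sin(2 * pi * 0.3 * seq_along(x) / fs_std)
  out2 <- ecg_baseline_remove(x + drift, fs_std, fc = 0.5)
  resid <- out2$corrected[core] - out$corrected[core]
  expect_lt(sqrt(2 * mean(resid^2)), 0.15 * A)   # residual drift amplitude
})
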