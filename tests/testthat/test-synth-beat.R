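test_that("pulse-beat truth fiducials match brute-force extrema scans", {
  for (g in 1:4) {
    b <- synth_ppw_beat(ppw_preset(g), fs_std)
    w <- b$waveform
    tr <- b$truth
    onset_idx <- tr$index[tr$point == "onset"]
    h1 <- tr[tr$point == "H1", ]
    # exhaustive scan oracle: H1 amplitude is max(waveform) - onset level
    expect_equal(h1$amp, max(w) - w[onset_idx], tolerance = 1e-12)
    expect_equal(h1$index, which.max(w))
    # landmark ordering and amplitude dominance
    idx <- tr$index[match(c("onset", "H1", "H2", "H3", "H4", "H5"), tr$point)]
    expect_true(all(diff(idx) > 0))
    expect_true(all(tr$amp[!tr$absent] <= h1$amp + 1e-12))
    expect_true(all(tr$amp[!tr$absent] >= 0))
  }
})

test_that("group-1 preset beats reproduce the published amplitude-ratio medians", {
  morph <- ppw_preset(1)
  set.seed(42)
  h3 <- h5 <- numeric(120)
  for (i in 1:120) {
    m <- morph
    m$a <- m$a * exp(rnorm(3, 0, 0.04))
    b <- synth_ppw_beat(m, fs_std)
    tr <- b$truth
    h1 <- tr$amp[tr$point == "H1"]
    h3[i] <- tr$amp[tr$point == "H3"] / h1
    h5[i] <- tr$amp[tr$point == "H5"] / h1
  }
  expect_lt(abs(median(h3) - 0.72), 0.05)
  expect_lt(abs(median(h5) - 0.38), 0.05)
})

test_that("single-bump morphology raises a degenerate-morphology error", {
  m <- ppw_preset(1)
  m$a[2:3] <- 0
  m$notch_depth <- 0
  expect_error(synth_ppw_beat(m, fs_std), class = "pf_degenerate_morphology")
})

test_that("morphology parameter validation enforces the invariants", {
  expect_error(ppw_morph(0.8, a = c(-1, 0.5, 0.3), mu = c(0.1, 0.2, 0.4),
                         s = c(0.3, 0.05, 0.06)), class = "pf_invalid_morph")
  expect_error(ppw_morph(0.8, a = c(1, 0.5, 0.3), mu = c(0.2, 0.1, 0.4),
                         s = c(0.3, 0.05, 0.06)), class = "pf_invalid_morph")
  expect_error(ecg_morph(0.8, amp = c(0.1, -0.1, 1, -0.2, 0.3),
                         center = c(-0.1, -0.02, 0, -0.01, 0.2),
                         width = rep(0.01, 5)), class = "pf_invalid_morph")
  expect_error(ecg_morph(0.8, amp = c(0.1, -1.2, 1, -0.2, 0.3),
                         center = c(-0.1, -0.02, 0, 0.02, 0.2),
                         width = rep(0.01, 5)), class = "pf_invalid_morph")
})

test_that("ECG beat truth: R at the waveform argmax, QRS at its published duration", {
  for (g in 1:4) {
    b <- synth_ecg_beat(ecg_preset(g), fs_std)
    tr <- b$truth
    expect_equal(tr$index[tr$point == "R"], which.max(b$waveform))
    qrs <- tr$t[tr$point == "QRS_off"] - tr$t[tr$point == "QRS_on"]
    ref <- pulsefuse:::pf_ecg_reference()
    expect_lt(abs(qrs - ref$median[ref$feature == "QRS" & ref$group == g]),
              0.005)
  }
})

test_that("a beat delineated through the standard ECG filters recovers the published QRS", {
  # noiseless 10-beat train, group 1; the full two-stage pipeline applies
  rrs <- rep(60 / 76.22, 10)
  x <- make_ecg_train(rrs, group = 1)
  st <- ecg_two_stage(x, fs_std)
  r <- detect_r_peaks(st$stage1, fs_std)
  fid <- delineate_beat(st$stage2, r[5], fs_std, rr = rrs[1])
  qrs <- fid$t[fid$point == "QRS_off"] - fid$t[fid$point == "QRS_on"]
  expect_lt(abs(qrs - 0.072), 0.005)
})

test_that("absent P wave is flagged in truth and by the delineator", {
  m <- ecg_preset(1)
  m$amp[1] <- 0
  b <- synth_ecg_beat(m, fs_std)
  tr <- b$truth
  expect_true(all(tr$absent[tr$point %in% c("P_on", "P_peak", "P_off")]))
  x <- rep(b$waveform, 8)
  st <- ecg_two_stage(x, fs_std)
  r <- detect_r_peaks(st$stage1, fs_std)
  fid <- delineate_beat(st$stage2, r[4], fs_std, rr = m$rr)
  expect_true(all(fid$absent[fid$point %in% c("P_on", "P_peak", "P_off")]))
})
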