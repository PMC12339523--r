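test_that("cycle detection recovers every onset of a noiseless train", {
  x <- make_ppw_train(rep(0.8, 10))
  onsets <- detect_cycles(x, fs_std)
  truth <- round(1 * fs_std) + round((0:10) * 0.8 * fs_std) + 1L
  for (o in truth[2:10]) {
    expect_lt(min(abs(onsets - o)) / fs_std, 0.005)
  }
  periods <- diff(onsets) / fs_std
  expect_true(all(periods > 0.4 & periods < 2.0))
})

test_that("flat or empty signals raise an unusable-record error", {
  expect_error(detect_cycles(rep(1, 5000), fs_std), class = "pf_unusable_record")
  expect_error(detect_cycles(rnorm(200), fs_std), class = "pf_unusable_record")
})

test_that("a symmetric triangle cycle yields H1 at the apex and flags the rest absent", {
  fs <- fs_std
  n <- round(0.8 * fs)
  x <- numeric(n)
  base <- round(0.3 * fs)
  apex <- round(0.40 * fs)
  ramp <- seq(0, 1, length.out = base / 2)
  x[(apex - base / 2):(apex - 1)] <- ramp
  x[apex:(apex + base / 2 - 1)] <- rev(ramp)
  fid <- delineate_cycle(x, 1L, n + 1L, fs)
  expect_equal(fid$index[fid$point == "H1"], which.max(x))
  expect_true(all(fid$absent[fid$point %in% c("H2", "H3", "H4", "H5")]))
})

test_that("triangle pulse widths match the closed-form geometry", {
  # width of a triangle of base b at level l is b * (1 - l / H1)
  fs <- fs_std
  periods <- rep(0.8, 6)
  npad <- fs
  beat <- numeric(round(0.8 * fs))
  base <- round(0.3 * fs)
  apex <- round(0.4 * fs)
  ramp <- seq(0, 1, length.out = base / 2)
  beat[(apex - base / 2):(apex - 1)] <- ramp
  beat[apex:(apex + base / 2 - 1)] <- rev(ramp)
  x <- c(seq(0.02, 0, length.out = npad), rep(beat, 6),
         seq(0, 0.02, length.out = npad))
  f <- extract_ppw_features(x, fs = fs, preprocess = FALSE)
  expect_equal(f$W1, 0.100, tolerance = 0.02)
  expect_equal(f$W2, 0.060, tolerance = 0.03)
  expect_lt(f$P_SDNN, 1)
})

test_that("pulse-rate variability reproduces the hand-computed formula values", {
  x <- make_ppw_train(c(0.800, 0.820, 0.790, 0.810))
  f <- extract_ppw_features(x, fs = fs_std, preprocess = FALSE, edge_trim = 0.4)
  expect_equal(f$P_SDNN, sd(c(800, 820, 790, 810)), tolerance = 0.08)
  expect_equal(f$P_rMSSD, sqrt(mean(diff(c(800, 820, 790, 810))^2)),
               tolerance = 0.08)
})

test_that("noiseless delineation recovers the generator fiducials exactly", {
  for (g in c(1, 3)) {
    rec <- synth_record(g, seed = 100 + g, duration = 12)
    sig <- rec$signal$ppw
    onsets <- detect_cycles(sig, rec$fs)
    truth <- rec$truth$ppw
    n_checked <- 0L
    for (b in unique(truth$beat)) {
      tb <- truth[truth$beat == b, ]
      o <- tb$index[tb$point == "onset"]
      j <- which.min(abs(onsets - o))
      if (j >= length(onsets) || abs(onsets[j] - o) > 0.01 * rec$fs) next
      fid <- delineate_cycle(sig, onsets[j], onsets[j + 1L], rec$fs)
      h1 <- tb$amp[tb$point == "H1"]
      for (pt in c("H1", "H2", "H3", "H4", "H5")) {
        it <- tb$index[tb$point == pt]
        id <- fid$index[fid$point == pt]
        if (is.na(it) || is.na(id)) next
        expect_lt(abs(id - it) / rec$fs, 0.005)
        expect_lt(abs(fid$amp[fid$point == pt] - tb$amp[tb$point == pt]),
                  0.02 * h1)
        n_checked <- n_checked + 1L
      }
    }
    expect_gt(n_checked, 30L)
  }
})

test_that("features are invariant to amplitude scaling and time shift", {
  rec <- synth_record(2, seed = 77, duration = 12)
  f1 <- extract_ppw_features(rec$signal$ppw, fs = rec$fs, preprocess = FALSE)
  f2 <- extract_ppw_features(5.3 * rec$signal$ppw, fs = rec$fs, preprocess = FALSE)
  time_cols <- c("T", "T1", "T4", "T5", "W1", "W2")
  ratio_cols <- c("H2_H1", "H3_H1", "H4_H1", "H5_H1", "T1_T", "T4_T",
                  "W1_T", "W2_T", "As_Ad")
  for (cc in c(time_cols, ratio_cols)) {
    expect_equal(f2[[cc]], f1[[cc]], tolerance = 1e-9, label = cc)
  }
  expect_equal(f2$H1, 5.3 * f1$H1, tolerance = 1e-9)
  # shifting the record start changes nothing but the edge cycles
  shift <- round(0.35 * rec$fs)
  f3 <- extract_ppw_features(rec$signal$ppw[-seq_len(shift)], fs = rec$fs,
                             preprocess = FALSE)
  for (cc in c(time_cols, ratio_cols)) {
    expect_equal(f3[[cc]], f1[[cc]], tolerance = 0.02, label = cc)
  }
})

test_that("structural identities hold: T = T4 + T5, W2 <= W1 <= T", {
  rec <- synth_record(4, seed = 13, duration = 12)
  f <- extract_ppw_features(rec)
  # per cycle the identity is exact; subject-level values are per-feature
  # medians, so it holds only approximately across cycles
  expect_equal(f$T, f$T4 + f$T5, tolerance = 0.01)
  expect_true(f$W2 <= f$W1 && f$W1 <= f$T)
  expect_gt(f$As_Ad, 0)
})

test_that("too few cycles raise an unusable-record error", {
  x <- make_ppw_train(rep(0.8, 2))
  expect_error(extract_ppw_features(x, fs = fs_std, preprocess = FALSE,
                                    min_cycles = 5L),
               class = "pf_unusable_record")
})
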