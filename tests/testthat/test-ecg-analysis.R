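test_that("R detection finds every beat of a clean train within 10 ms", {
  rrs <- rep(0.8, 9)
  x <- make_ecg_train(rrs)                  # 10 beats (9 RR intervals), 1 s pads
  st <- ecg_two_stage(x, fs_std)
  r <- detect_r_peaks(st$stage1, fs_std)
  truth_r <- round((1 + 0.26 + 0.8 * (0:9)) * fs_std) + 1L
  expect_length(r, 10L)
  expect_true(all(abs(r - truth_r) / fs_std <= 0.010))
})

test_that("flat signals raise an unusable-record error", {
  expect_error(detect_r_peaks(rep(0, 8000), fs_std), class = "pf_unusable_record")
})

test_that("50 Hz interference at 20% of R does not change the detected beats", {
  x <- make_ecg_train(rep(0.8, 10))
  t <- (seq_along(x) - 1) / fs_std
  noisy <- x + 0.2 * sin(2 * pi * 50 * t)
  r_clean <- detect_r_peaks(ecg_two_stage(x, fs_std)$stage1, fs_std)
  r_noisy <- detect_r_peaks(ecg_two_stage(noisy, fs_std)$stage1, fs_std)
  expect_equal(length(r_noisy), length(r_clean))
  expect_true(all(abs(r_noisy - r_clean) / fs_std <= 0.005))
})

test_that("beat delineation recovers PR and QT against generator truth", {
  rec <- synth_record(1, seed = 201, duration = 12)
  pe <- preprocess_ecg(rec$signal$ecg, rec$fs)
  r <- detect_r_peaks(pe$stage1, rec$fs)
  truth <- rec$truth$ecg
  pr_err <- qt_err <- c()
  for (b in unique(truth$beat)) {
    tb <- truth[truth$beat == b, ]
    rt <- tb$index[tb$point == "R"]
    j <- which.min(abs(r - rt))
    if (abs(r[j] - rt) > 0.02 * rec$fs) next
    rr_loc <- if (j < length(r)) (r[j + 1] - r[j]) / rec$fs else 0.8
    fid <- delineate_beat(pe$stage2, r[j], rec$fs, rr = rr_loc)
    if (is.null(fid)) next
    gv <- function(d, p) d$index[d$point == p]
    pr_err <- c(pr_err, ((gv(fid, "QRS_on") - gv(fid, "P_on")) -
                         (gv(tb, "QRS_on") - gv(tb, "P_on"))) / rec$fs)
    qt_err <- c(qt_err, ((gv(fid, "T_off") - gv(fid, "QRS_on")) -
                         (gv(tb, "T_off") - gv(tb, "QRS_on"))) / rec$fs)
  }
  expect_gt(length(pr_err), 8)
  expect_lt(abs(median(pr_err)), 0.010)
  expect_lt(abs(median(qt_err)), 0.015)
})

test_that("HRV features reproduce the hand-computed formula values", {
  x <- make_ecg_train(c(0.800, 0.820, 0.790, 0.810))
  f <- extract_ecg_features(x, fs = fs_std, preprocess = FALSE, edge_trim = 0.3)
  expect_equal(f$mean_RR, 805, tolerance = 0.1)
  expect_equal(f$HR, 74.53, tolerance = 0.05)
  expect_equal(f$SDNN, 12.91, tolerance = 0.08)
  expect_equal(f$RMSSD, 23.80, tolerance = 0.08)
  # HR x mean RR identity within 0.1%
  expect_lt(abs(f$HR * f$mean_RR / 60000 - 1), 0.001)
})

test_that("duration features are invariant to amplitude scaling", {
  rec <- synth_record(2, seed = 301, duration = 12)
  f1 <- extract_ecg_features(rec$signal$ecg, fs = rec$fs)
  f2 <- extract_ecg_features(4.2 * rec$signal$ecg, fs = rec$fs)
  for (cc in c("P_seg", "QRS_seg", "T_seg", "PR_seg", "ST_seg", "PR_int",
               "QT_int", "HR", "SDNN", "RMSSD")) {
    expect_equal(f2[[cc]], f1[[cc]], tolerance = 0.02, label = cc)
  }
  expect_equal(f2$R_amp, 4.2 * f1$R_amp, tolerance = 0.02)
})

test_that("variability statistics are non-negative and zero only for constant RR", {
  rec <- synth_record(1, seed = 31, duration = 12)
  f <- extract_ecg_features(rec)
  expect_gt(f$SDNN, 0)
  expect_gt(f$RMSSD, 0)
  expect_lt(abs(f$HR * f$mean_RR / 60000 - 1), 0.001)
})

test_that("too few beats raise an unusable-record error", {
  x <- make_ecg_train(rep(0.8, 4))
  expect_error(extract_ecg_features(x, fs = fs_std, min_beats = 10L),
               class = "pf_unusable_record")
})
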