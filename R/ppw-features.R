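# Pulse-cycle detection, fiducial delineation and time-domain features.

#' Detect pulse-cycle onsets (troughs)
#'
#' Finds the onset trough of every pulse cycle on a low-pass-filtered PPW
#' signal: systolic peaks are located with an adaptive amplitude threshold
#' and a 0.4 s minimum separation, and each onset is the minimum between
#' consecutive peaks (the trough preceding the steep systolic upstroke).
#'
#' @param x Low-pass-filtered PPW signal.
#' @param fs Sampling frequency (Hz).
#' @return Strictly increasing integer vector of onset indices.
#' @export
detect_cycles <- function(x, fs) {
  n <- length(x)
  if (n < fs) pf_abort("record too short", "pf_unusable_record")
  rng <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  if (diff(rng) < 1e-12) {
    pf_abort("no pulse cycles detected (flat signal)", "pf_unusable_record")
  }
  thr <- mean(rng)
  cand <- local_maxima(x)
  cand <- cand[x[cand] > thr]
  if (length(cand) < 2L) {
    pf_abort("no pulse cycles detected", "pf_unusable_record")
  }
  # greedy minimum-distance suppression, largest peaks first
  min_gap <- round(0.4 * fs)
  keep <- integer()
  for (i in cand[order(x[cand], decreasing = TRUE)]) {
    if (all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  peaks <- sort(keep)

  # trough = the *last* point of the near-minimal region between two
  # peaks: pulse feet can be nearly flat, where a bare argmin floats; the
  # right edge of the flat bottom abuts the systolic upstroke
  eps <- 1e-3 * diff(rng)
  last_min <- function(lo, hi) {
    seg <- x[lo:hi]
    lo - 1L + max(which(seg <= min(seg) + eps))
  }
  onsets <- integer(length(peaks))
  first_lo <- max(1L, peaks[1] - round(0.6 * fs))
  onsets[1] <- last_min(first_lo, peaks[1])
  if (length(peaks) > 1L) {
    for (i in seq_len(length(peaks) - 1L)) {
      onsets[i + 1L] <- last_min(peaks[i], peaks[i + 1L])
    }
  }
  onsets <- unique(onsets)
  periods <- diff(onsets) / fs
  ok <- periods > 0.4 & periods < 2.0
  if (sum(ok) < 3L) {
    pf_abort("fewer than 3 complete pulse cycles; record unusable",
             "pf_unusable_record")
  }
  onsets
}

#' Delineate one pulse cycle
#'
#' Locates the five pulse landmarks inside `[onset, next_onset)`:
#' H1 = global maximum (percussion peak); H4 = most prominent local minimum
#' after H1 within 0.15--0.6 of the cycle (dicrotic notch); H3 = largest
#' local maximum between H1 and the notch (tidal peak; first-derivative
#' inflection as fallback); H2 = first zero of the second derivative on the
#' descending limb between H1 and H3 (pre-tidal shoulder); H5 = largest
#' local maximum after the notch (dicrotic peak). Amplitudes are measured
#' above the onset level; missing landmarks are flagged absent.
#'
#' @param x PPW signal (filtered and baseline-corrected).
#' @param onset,next_onset Cycle boundary indices from [detect_cycles()].
#' @param fs Sampling frequency (Hz).
#' @return Tibble with columns `point`, `index` (absolute), `t` (s from
#'   onset), `amp` (above onset level), `absent`.
#' @export
delineate_cycle <- function(x, onset, next_onset, fs) {
  if (onset < 1L || next_onset > length(x) + 1L || next_onset - onset < 10L) {
    pf_abort("cycle out of signal bounds", "pf_invalid_argument")
  }
  seg <- x[onset:(next_onset - 1L)]
  ppw_core_to_tibble(locate_ppw_core(seg, fs, strict = FALSE), seg, fs,
                     offset = onset - 1L)
}

# feature names of the per-cycle PPW vector
pf_ppw_cycle_names <- c("H1", "H2", "H3", "H4", "H5", "T", "T1", "T2", "T3",
                        "T4", "T5", "W1", "W2", "As", "Ad")

# per-cycle feature vector (named numeric, NA where undefined)
ppw_cycle_feature_vec <- function(seg, fs, core) {
  base <- seg[core$onset]
  period <- length(seg) / fs
  amp <- function(i) if (is.na(i)) NA_real_ else seg[i] - base
  tt <- function(i) if (is.na(i)) NA_real_ else (i - core$onset) / fs
  h1 <- amp(core$H1)
  w1 <- w2 <- as_ <- ad <- NA_real_
  if (is.finite(h1) && h1 > 0) {
    w1 <- time_above_level(seg, base + (2 / 3) * h1, 1 / fs)
    w2 <- time_above_level(seg, base + (4 / 5) * h1, 1 / fs)
  }
  if (!is.na(core$H4)) {
    as_ <- trapz_area(seg[core$onset:core$H4] - base, 1 / fs)
    ad <- trapz_area(seg[core$H4:length(seg)] - base, 1 / fs)
  }
  t4 <- tt(core$H4)
  c(H1 = h1, H2 = amp(core$H2), H3 = amp(core$H3), H4 = amp(core$H4),
    H5 = amp(core$H5), T = period, T1 = tt(core$H1), T2 = tt(core$H2),
    T3 = tt(core$H3), T4 = t4, T5 = period - t4, W1 = w1, W2 = w2,
    As = as_, Ad = ad)
}

#' Extract the subject-level pulse feature vector
#'
#' Runs the pulse pipeline on one record: (optionally) 8 Hz low-pass +
#' cubic-spline baseline removal, cycle detection, per-cycle delineation
#' and feature computation, then aggregation across cycles by the median
#' (the "typical cycle"). Pulse-rate variability (P-SDNN, P-rMSSD, in ms)
#' is computed from the inter-onset period series.
#'
#' @param record A `pf_record`, or a numeric PPW vector (then `fs` must be
#'   given).
#' @param fs Sampling frequency, required when `record` is a bare vector.
#' @param preprocess Apply filtering and baseline removal first. Set to
#'   `FALSE` for signals that are already filtered and baseline-free.
#' @param min_cycles Minimum number of valid cycles (error below).
#' @param edge_trim Seconds excluded at each end of the record.
#' @return One-row tibble: `H1..H5`, `T`, `T1..T5`, `W1`, `W2`, `As`, `Ad`,
#'   amplitude/time ratios (`H2_H1`, ..., `As_Ad`), `P_rMSSD`, `P_SDNN`
#'   (ms), `n_cycles`.
#' @export
extract_ppw_features <- function(record, fs = NULL, preprocess = TRUE,
                                 min_cycles = 3L, edge_trim = 0.5) {
  if (inherits(record, "pf_record")) {
    x <- record$signal$ppw; fs <- record$fs
  } else {
    x <- as.numeric(record)
    if (is.null(fs)) pf_abort("fs required for a bare signal", "pf_invalid_argument")
  }
  if (preprocess) {
    pp <- preprocess_ppw(x, fs)
    sig <- pp$corrected
    onsets <- detect_cycles(sig, fs)
  } else {
    sig <- x
    onsets <- detect_cycles(sig, fs)
  }
  n <- length(sig)
  onsets <- onsets[onsets >= edge_trim * fs & onsets <= n - edge_trim * fs]
  if (length(onsets) < min_cycles + 1L) {
    pf_abort("fewer than the minimum number of complete cycles",
             "pf_unusable_record")
  }
  periods <- diff(onsets) / fs
  ok <- periods > 0.4 & periods < 2.0

  rows <- list()
  for (i in which(ok)) {
    seg <- sig[onsets[i]:(onsets[i + 1L] - 1L)]
    core <- locate_ppw_core(seg, fs, strict = FALSE)
    f <- ppw_cycle_feature_vec(seg, fs, core)
    if (is.finite(f[["H1"]]) && f[["H1"]] > 0) rows[[length(rows) + 1L]] <- f
  }
  if (length(rows) < min_cycles) {
    pf_abort("fewer than the minimum number of valid cycles",
             "pf_unusable_record")
  }
  # pulse-to-pulse period series for the variability statistics, taken
  # between successive maximum-upslope landmarks (the systolic upstroke is
  # the sharpest, most noise-robust part of the cycle; the spacing equals
  # the inter-onset spacing)
  d1 <- diff(sig)
  upstroke <- vapply(seq_along(onsets), function(i) {
    hi <- min(onsets[i] + round(0.30 * fs), length(d1))
    onsets[i] - 1L + which.max(d1[onsets[i]:hi])
  }, numeric(1))
  up_ms <- diff(upstroke) / fs * 1000
  up_ms <- up_ms[up_ms > 400 & up_ms < 2000]

  per <- do.call(rbind, rows)
  med <- apply(per, 2, stats::median, na.rm = TRUE)
  rat <- cbind(H2_H1 = per[, "H2"] / per[, "H1"],
               H3_H1 = per[, "H3"] / per[, "H1"],
               H4_H1 = per[, "H4"] / per[, "H1"],
               H5_H1 = per[, "H5"] / per[, "H1"],
               T1_T = per[, "T1"] / per[, "T"],
               T4_T = per[, "T4"] / per[, "T"],
               T1_T4 = per[, "T1"] / per[, "T4"],
               T5_T4 = per[, "T5"] / per[, "T4"],
               W1_T = per[, "W1"] / per[, "T"],
               W2_T = per[, "W2"] / per[, "T"],
               As_Ad = per[, "As"] / per[, "Ad"])
  med_rat <- apply(rat, 2, stats::median, na.rm = TRUE)
  out <- c(med, med_rat, P_rMSSD = rmssd(up_ms), P_SDNN = sdnn(up_ms),
           n_cycles = nrow(per))
  tibble::as_tibble(as.list(out))
}
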