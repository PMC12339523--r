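# R-peak detection, P-QRS-T delineation and ECG time-domain features.

#' Detect R peaks on the stage-1 (40 Hz) ECG signal
#'
#' Classical derivative-energy detector: the squared first difference is
#' integrated over a 150 ms moving window, candidate beats are local maxima
#' of the integrated energy above an adaptive threshold, a 0.25 s
#' refractory period suppresses double detections, and each candidate is
#' refined to the local maximum of the stage-1 signal within +/-60 ms.
#'
#' @param stage1 Stage-1 filtered ECG from [ecg_two_stage()].
#' @param fs Sampling frequency (Hz).
#' @param threshold Fraction of the 99th percentile of integrated energy
#'   used as detection threshold.
#' @return Strictly increasing integer vector of R-peak indices.
#' @export
detect_r_peaks <- function(stage1, fs, threshold = 0.2) {
  n <- length(stage1)
  if (n < fs) pf_abort("record too short", "pf_unusable_record")
  # restrict the energy computation to the QRS band (5-15 Hz) so that
  # residual EMG-band noise in stage 1 cannot trigger spurious beats
  rng <- diff(range(stage1))
  if (rng < 1e-12) pf_abort("no beats detected (flat signal)", "pf_unusable_record")
  bp <- apply_butter(stage1, fs, 2L, 15, zero_phase = TRUE) -
        apply_butter(stage1, fs, 2L, 5, zero_phase = TRUE)
  d <- diff(bp)
  e <- d^2
  win <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(e, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0
  top <- stats::quantile(integ, 0.99, names = FALSE)
  if (top < 1e-20) pf_abort("no beats detected (flat signal)", "pf_unusable_record")
  thr <- threshold * top
  cand <- local_maxima(integ)
  cand <- cand[integ[cand] > thr]
  if (length(cand) < 3L) {
    pf_abort("fewer than 3 R peaks detected; record unusable",
             "pf_unusable_record")
  }
  refr <- round(0.25 * fs)
  keep <- integer()
  for (i in cand[order(integ[cand], decreasing = TRUE)]) {
    if (all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  # refine to the stage-1 local maximum
  half <- as.integer(round(0.06 * fs))
  r <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo - 1L + which.max(stage1[lo:hi]))
  }, integer(1))
  r <- sort(unique(r))
  if (length(r) < 3L) {
    pf_abort("fewer than 3 R peaks detected; record unusable",
             "pf_unusable_record")
  }
  r
}

# walk outward from `from` (exclusive) towards `bound` until |x - iso|
# stays below thr for `run` consecutive samples
walk_until_below <- function(x, from, bound, iso, thr, run = 3L) {
  dir <- sign(bound - from)
  if (dir == 0) return(from)
  count <- 0L
  j <- from
  while (j != bound) {
    j <- j + dir
    if (abs(x[j] - iso) < thr) {
      count <- count + 1L
      if (count >= run) return(as.integer(j - dir * (run - 1L)))
    } else count <- 0L
  }
  as.integer(bound)
}

# core beat delineator; returns a named list of indices (NA = absent)
# plus the isoelectric level, or NULL when windows leave the record
delineate_beat_core <- function(stage2, r, fs, rr = 0.8, qrs_frac = 0.03,
                                wave_frac = 0.025, p_frac = 0.04,
                                p_floor = 0.05) {
  n <- length(stage2)
  ms <- function(x) as.integer(round(x * fs / 1000))
  if (r - ms(350) < 1L || r + ms(700) > n) return(NULL)

  w80 <- ms(80)
  q <- (r - w80) - 1L + which.min(stage2[(r - w80):(r - 2L)])
  s <- r + 1L + which.min(stage2[(r + 2L):(r + w80)])

  # lightly smoothed copy for the threshold walks: suppresses residual
  # near-20 Hz noise that would otherwise keep |x - iso| above threshold
  k_sm <- max(3L, ms(10))
  sm <- as.numeric(stats::filter(stage2, rep(1 / k_sm, k_sm), sides = 2))
  sm[is.na(sm)] <- stage2[is.na(sm)]

  # provisional isoelectric level: flat region ahead of the P wave
  iso0 <- stats::median(stage2[(r - ms(320)):(r - ms(260))])

  # QRS bounds: walk outward from R until the signal returns to within
  # qrs_frac of the R amplitude above the isoelectric level (sustained, so
  # a steep zero crossing inside the complex cannot trigger it)
  thr_qrs <- qrs_frac * (stage2[r] - iso0)
  qrs_on <- walk_until_below(sm, r, max(1L, r - ms(150)), iso0, thr_qrs)
  qrs_off <- walk_until_below(sm, r, min(n, r + ms(150)), iso0, thr_qrs)

  # P wave. Each bound walk references the floor (low quantile of the
  # smoothed signal) of its own search window: residual baseline ripple
  # offsets the flat segments from the global isoelectric estimate by more
  # than the small wave thresholds, so a local reference is required.
  pwin <- (r - ms(300)):(r - w80)
  p <- pwin[which.max(stage2[pwin])]
  r_amp0 <- stage2[r] - iso0
  p_absent <- (stage2[p] - iso0) < p_floor * r_amp0
  if (!p_absent) {
    thr_p <- p_frac * (stage2[p] - iso0)
    pl_bound <- max(1L, r - ms(340))
    p_on <- walk_until_below(sm, p, pl_bound, stats::quantile(sm[pl_bound:p], 0.2, names = FALSE), thr_p)
    pr_bound <- max(p + 1L, qrs_on - 1L)
    p_off <- walk_until_below(sm, p, pr_bound, stats::quantile(sm[p:pr_bound], 0.2, names = FALSE), thr_p)
    iso <- stage2[p_on]
  } else {
    p_on <- p_off <- NA_integer_
    iso <- iso0
  }

  # T wave
  t_hi <- r + min(ms(1000 * 0.6 * rr), ms(450))
  twin <- (r + ms(120)):min(t_hi, n)
  tp <- twin[which.max(stage2[twin])]
  thr_t <- wave_frac * (stage2[tp] - iso0)
  t_on <- walk_until_below(sm, tp, qrs_off, stats::quantile(sm[qrs_off:tp], 0.2, names = FALSE), thr_t)
  # the offset search must stop before the next beat's P wave
  t_off_hi <- min(tp + ms(350), r + ms(max(350, 1000 * rr - 320)), n)
  t_off <- walk_until_below(sm, tp, t_off_hi, stats::quantile(sm[tp:t_off_hi], 0.2, names = FALSE), thr_t)

  list(idx = c(P_on = if (p_absent) NA_integer_ else p_on,
               P_peak = if (p_absent) NA_integer_ else as.integer(p),
               P_off = if (p_absent) NA_integer_ else p_off,
               Q = as.integer(q), R = as.integer(r), S = as.integer(s),
               QRS_on = qrs_on, QRS_off = qrs_off,
               T_on = t_on, T_peak = as.integer(tp), T_off = t_off),
       iso = iso)
}

#' Delineate one ECG beat on the stage-2 (20 Hz) signal
#'
#' Using a detected R peak as reference: Q and S are the signal minima
#' within +/-80 ms of R; QRS onset/offset lie where the signal returns to
#' within `qrs_frac` of the R amplitude beyond Q/S; the P peak is the
#' maximum in `[R-300, R-80]` ms and the T peak the maximum in
#' `[R+120, R+min(0.6 RR, 450)]` ms; P/T onsets and offsets lie where the
#' signal returns to within `wave_frac` of the wave amplitude above the
#' isoelectric level. Amplitudes are reported relative to the P-onset
#' (isoelectric) level.
#'
#' @param stage2 Stage-2 filtered ECG.
#' @param r R-peak index (from [detect_r_peaks()]).
#' @param fs Sampling frequency (Hz).
#' @param rr Local RR estimate in seconds (bounds the T-peak window).
#' @param qrs_frac Amplitude threshold for the QRS bounds, as a fraction of
#'   the R amplitude above the isoelectric level.
#' @param wave_frac Amplitude threshold for T bounds, as a fraction of
#'   the wave's peak amplitude above the isoelectric level.
#' @param p_frac Amplitude threshold for P bounds (larger than `wave_frac`
#'   because the P wave is small relative to residual noise).
#' @param p_floor Minimum P amplitude (fraction of R amplitude) below which
#'   the P wave is flagged absent.
#' @return Tibble (`point`, `index`, `t`, `amp`, `absent`) or `NULL` when
#'   the beat's search windows fall outside the record.
#' @export
delineate_beat <- function(stage2, r, fs, rr = 0.8, qrs_frac = 0.03,
                           wave_frac = 0.025, p_frac = 0.04, p_floor = 0.05) {
  core <- delineate_beat_core(stage2, r, fs, rr, qrs_frac, wave_frac, p_frac,
                              p_floor)
  if (is.null(core)) return(NULL)
  idx <- core$idx
  tibble::tibble(point = names(idx), index = unname(idx),
                 t = (unname(idx) - 1L) / fs,
                 amp = ifelse(is.na(idx), NA_real_,
                              stage2[ifelse(is.na(idx), 1L, idx)] - core$iso),
                 absent = is.na(idx))
}

#' Extract the subject-level ECG feature vector
#'
#' Runs the ECG pipeline on one record: baseline removal and two-stage
#' filtering (optional), R detection on stage 1, per-beat P-QRS-T
#' delineation on stage 2, aggregation of per-beat amplitudes and durations
#' by the median, and heart-rate variability (SDNN, RMSSD, mean RR, all ms)
#' from the RR series.
#'
#' @param record A `pf_record`, or a numeric ECG vector (then `fs` must be
#'   given).
#' @param fs Sampling frequency, required for a bare vector.
#' @param preprocess Apply baseline removal + two-stage filtering first;
#'   with `FALSE` only the two-stage filter is applied (signal assumed
#'   drift-free).
#' @param min_beats Minimum number of delineated beats (error below).
#' @param edge_trim Seconds excluded at each end of the record.
#' @param ... Passed to [delineate_beat()].
#' @return One-row tibble: wave amplitudes (`P_amp` ... `T_amp`), durations
#'   (`P_seg`, `QRS_seg`, `T_seg`, `PR_seg`, `ST_seg`, seconds), intervals
#'   (`PR_int`, `QT_int`, `RR_int`, seconds), `HR` (beats/min), `SDNN`,
#'   `RMSSD`, `mean_RR` (ms), `n_beats`.
#' @export
extract_ecg_features <- function(record, fs = NULL, preprocess = TRUE,
                                 min_beats = 3L, edge_trim = 0.5, ...) {
  if (inherits(record, "pf_record")) {
    x <- record$signal$ecg; fs <- record$fs
  } else {
    x <- as.numeric(record)
    if (is.null(fs)) pf_abort("fs required for a bare signal", "pf_invalid_argument")
  }
  if (preprocess) {
    pp <- preprocess_ecg(x, fs)
    stage1 <- pp$stage1; stage2 <- pp$stage2
  } else {
    st <- ecg_two_stage(x, fs)
    stage1 <- st$stage1; stage2 <- st$stage2
  }
  r <- detect_r_peaks(stage1, fs)
  rr_ms <- diff(r) / fs * 1000
  n <- length(x)
  usable <- r[r >= edge_trim * fs & r <= n - edge_trim * fs]

  rows <- list()
  for (i in seq_along(usable)) {
    k <- match(usable[i], r)
    rr_loc <- if (k < length(r)) (r[k + 1L] - r[k]) / fs
              else if (k > 1L) (r[k] - r[k - 1L]) / fs else 0.8
    core <- delineate_beat_core(stage2, usable[i], fs, rr = rr_loc, ...)
    if (is.null(core)) next
    idx <- core$idx
    amp <- function(p) if (is.na(idx[p])) NA_real_ else unname(stage2[idx[p]] - core$iso)
    tt <- function(p) if (is.na(idx[p])) NA_real_ else unname((idx[p] - 1) / fs)
    rows[[length(rows) + 1L]] <- c(
      P_amp = amp("P_peak"), Q_amp = amp("Q"), R_amp = amp("R"),
      S_amp = amp("S"), T_amp = amp("T_peak"),
      P_seg = tt("P_off") - tt("P_on"),
      QRS_seg = tt("QRS_off") - tt("QRS_on"),
      T_seg = tt("T_off") - tt("T_on"),
      PR_seg = tt("QRS_on") - tt("P_off"),
      ST_seg = tt("T_on") - tt("QRS_off"),
      PR_int = tt("QRS_on") - tt("P_on"),
      QT_int = tt("T_off") - tt("QRS_on"))
  }
  if (length(rows) < min_beats) {
    pf_abort("fewer than the minimum number of delineated beats",
             "pf_unusable_record")
  }
  per <- do.call(rbind, rows)
  med <- apply(per, 2, stats::median, na.rm = TRUE)
  mean_rr <- mean(rr_ms)
  out <- c(med, RR_int = mean_rr / 1000, HR = 60000 / mean_rr,
           SDNN = sdnn(rr_ms), RMSSD = rmssd(rr_ms), mean_RR = mean_rr,
           n_beats = nrow(per))
  tibble::as_tibble(as.list(out))
}
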