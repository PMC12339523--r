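# Single-beat synthesis with exact ground-truth fiducials.

# evaluate the three PPW bump components (+ notch deepener) at times t (s)
ppw_bump_values <- function(t, morph) {
  a <- morph$a; mu <- morph$mu; s <- morph$s
  perc <- ifelse(t > 0, a[1] * exp(-(log(pmax(t, 1e-12) / mu[1]))^2 / (2 * s[1]^2)), 0)
  tidal <- a[2] * exp(-(t - mu[2])^2 / (2 * s[2]^2))
  dicro <- a[3] * exp(-(t - mu[3])^2 / (2 * s[3]^2))
  mn <- (mu[2] + mu[3]) / 2
  sn <- (mu[3] - mu[2]) / 5
  notch <- morph$notch_depth * a[1] * exp(-(t - mn)^2 / (2 * sn^2))
  perc + tidal + dicro - notch
}

# raw bump sum corrected so the cycle starts and ends at zero. The start
# value is removed with a decaying ramp and the end value with a quartic
# ramp concentrated near the cycle end: a linear end-ramp can overshoot the
# slowly decaying tail and push it below zero mid-diastole, which detaches
# the inter-beat minimum from the beat boundary; the quartic ramp keeps the
# tail positive and monotone into the next onset.
ppw_cycle_values <- function(t, morph) {
  w <- ppw_bump_values(t, morph)
  w0 <- ppw_bump_values(0, morph)
  wT <- ppw_bump_values(morph$period, morph)
  u <- pmin(pmax(t / morph$period, 0), 1)
  # small "foot" pedestal: rises fast over the first 5% of the cycle and is
  # absorbed by the quartic end ramp, so the cycle has a sharp V-shaped
  # minimum exactly at its boundary (the bump tails alone leave a nearly
  # flat, slightly wiggly trough on which a minimum search is ill-posed)
  delta <- 0.02 * morph$a[1]
  foot <- delta * pmin(u / 0.05, 1)
  w + foot - w0 * (1 - u) - (wT + delta) * u^4
}

#' Synthesize one noiseless pulse cycle with ground-truth fiducials
#'
#' Builds a single PPW cycle from [ppw_morph()] parameters and locates the
#' five canonical landmarks (percussion peak H1, pre-tidal shoulder H2,
#' tidal peak H3, dicrotic notch H4, dicrotic peak H5) numerically on the
#' noiseless waveform by derivative sign-change search.
#'
#' @param morph A [ppw_morph()] object.
#' @param fs Sampling frequency in Hz.
#' @return A list with `waveform` (numeric vector, one cycle), `truth`
#'   (tibble of fiducials: point, index, t, amp, absent), `fs`, `period`.
#' @export
synth_ppw_beat <- function(morph, fs) {
  stopifnot(inherits(morph, "ppw_morph"))
  assert_scalar_num(fs, "fs", lower = 1)
  n <- round(morph$period * fs)
  t <- (seq_len(n) - 1) / fs
  w <- ppw_cycle_values(t, morph)
  truth <- ppw_core_to_tibble(locate_ppw_core(w, fs, strict = TRUE), w, fs)
  structure(list(waveform = w, truth = truth, fs = fs, period = morph$period),
            class = "pf_ppw_beat")
}

# Locate pulse fiducials on one cycle by derivative sign-change search.
# Returns a list of indices (NA when absent) plus the onset baseline.
# With strict = TRUE a missing landmark raises a degenerate-morphology
# error naming it. Shared by generator ground truth and analysis-side
# delineation (strict = FALSE).
locate_ppw_core <- function(x, fs, strict = FALSE) {
  n <- length(x)
  if (n < 10L) pf_abort("cycle too short to delineate", "pf_invalid_argument")
  fail <- function(landmark) {
    if (strict) {
      pf_abort(paste0("degenerate morphology: missing ", landmark),
               "pf_degenerate_morphology")
    }
    NA_integer_
  }
  onset <- which.min(x[seq_len(max(3L, round(0.15 * n)))])
  i1 <- onset - 1L + which.max(x[onset:n])
  if (i1 <= onset || x[i1] <= x[onset]) {
    i1 <- fail("percussion peak")
  }

  period <- (n - onset + 1) / fs
  lmin <- local_minima(x); lmin <- lmin[lmin > i1 & lmin < n - 2L]
  lmax <- local_maxima(x); lmax <- lmax[lmax > i1 & lmax < n - 2L]

  # dicrotic notch: most prominent local minimum in (0.15, 0.6) * period
  i4 <- NA_integer_
  if (!is.na(i1)) {
    tl <- (lmin - onset) / fs
    win <- lmin[tl > 0.15 * period & tl < 0.60 * period]
    if (length(win) > 0L) {
      prom <- vapply(win, function(m) {
        min(max(x[i1:m]), max(x[m:n])) - x[m]
      }, numeric(1))
      i4 <- win[which.max(prom)]
    } else fail("dicrotic notch")
  }

  # dicrotic peak: largest local maximum after the notch
  i5 <- NA_integer_
  if (!is.na(i4)) {
    after <- lmax[lmax > i4]
    if (length(after) > 0L) i5 <- after[which.max(x[after])] else fail("dicrotic peak")
  }

  # tidal peak: largest local maximum between H1 and the notch; fall back
  # to the first-derivative inflection (least-negative slope) if none
  i3 <- NA_integer_; h3_fallback <- FALSE
  if (!is.na(i4) && !is.na(i1)) {
    between <- lmax[lmax > i1 & lmax < i4]
    if (length(between) > 0L) {
      i3 <- between[which.max(x[between])]
    } else {
      d1 <- diff(x)
      if (i4 - i1 > 6L) {
        seg <- seq(i1 + 2L, i4 - 2L)
        dmax <- local_maxima(d1[seg])
        if (length(dmax) > 0L) { i3 <- seg[dmax[1L]]; h3_fallback <- TRUE }
      }
      if (is.na(i3)) fail("tidal peak")
    }
  }

  # pre-tidal shoulder: first zero of the second derivative (concave ->
  # convex) on the descending limb between H1 and the tidal wave
  i2 <- NA_integer_
  if (!is.na(i3) && !is.na(i1) && i3 - i1 > 4L) {
    d2 <- diff(x, differences = 2L)
    tol <- 1e-9 * max(abs(x))
    seg <- seq(i1, i3 - 2L)
    neg <- d2[seg] < -tol
    pos <- d2[seg + 1L] >= tol
    hit <- which(neg & pos)
    if (length(hit) > 0L) i2 <- seg[hit[1L]] + 1L
  }
  if (is.na(i2) && !h3_fallback) fail("pre-tidal shoulder")
  if (is.na(i2) && !is.na(i3)) i2 <- i3  # shoulder collapses onto tidal inflection

  list(onset = onset, H1 = i1, H2 = i2, H3 = i3, H4 = i4, H5 = i5)
}

# fiducial index list -> user-facing tibble (times from onset, amplitudes
# above the onset level)
ppw_core_to_tibble <- function(core, x, fs, offset = 0L) {
  idx <- c(core$onset, core$H1, core$H2, core$H3, core$H4, core$H5)
  base <- x[core$onset]
  tibble::tibble(
    point = c("onset", "H1", "H2", "H3", "H4", "H5"),
    index = idx + offset,
    t = (idx - core$onset) / fs,
    amp = x[idx] - base,
    absent = is.na(idx))
}

# evaluate the five-Gaussian ECG beat at times t (s), R peak at r_off
ecg_beat_values <- function(t, morph, r_off) {
  w <- numeric(length(t))
  for (i in 1:5) {
    if (morph$amp[i] == 0) next
    c_i <- r_off + morph$center[i]
    w <- w + morph$amp[i] * exp(-(t - c_i)^2 / (2 * morph$width[i]^2))
  }
  w
}

#' Synthesize one noiseless ECG beat with ground-truth fiducials
#'
#' Builds a single beat as a sum of five Gaussian waves (P, Q, R, S, T) and
#' returns ground truth: wave peaks located numerically on the summed
#' waveform, and onsets/offsets at the points where each wave's component
#' falls to 1% of its peak. Waves with zero amplitude are flagged absent.
#'
#' @param morph An [ecg_morph()] object.
#' @param fs Sampling frequency in Hz.
#' @param r_offset Time of the R peak from beat start (s).
#' @return A list with `waveform`, `truth` (tibble: point, index, t, amp,
#'   absent), `fs`, `rr`, `r_offset`.
#' @export
synth_ecg_beat <- function(morph, fs, r_offset = 0.26) {
  stopifnot(inherits(morph, "ecg_morph"))
  assert_scalar_num(fs, "fs", lower = 1)
  n <- round(morph$rr * fs)
  t <- (seq_len(n) - 1) / fs
  w <- ecg_beat_values(t, morph, r_offset)
  truth <- ecg_beat_truth(morph, fs, r_offset, n, w)
  structure(list(waveform = w, truth = truth, fs = fs, rr = morph$rr,
                 r_offset = r_offset),
            class = "pf_ecg_beat")
}

# ground-truth fiducials of one synthetic ECG beat (times in s from beat
# start; amplitudes of the waveform relative to the zero isoelectric level)
ecg_beat_truth <- function(morph, fs, r_off, n, w) {
  k <- pf_kappa
  nm <- c("P", "Q", "R", "S", "T")
  present <- morph$amp != 0
  idx_of <- function(tt) min(max(as.integer(round(tt * fs) + 1L), 1L), n)

  peak_idx <- function(i) {
    c_i <- r_off + morph$center[i]
    seg <- idx_of(c_i - 2 * morph$width[i]):idx_of(c_i + 2 * morph$width[i])
    if (morph$amp[i] > 0) seg[which.max(w[seg])] else seg[which.min(w[seg])]
  }

  points <- c("P_on", "P_peak", "P_off", "Q", "R", "S",
              "T_on", "T_peak", "T_off", "QRS_on", "QRS_off")
  idx <- rep(NA_integer_, length(points))
  names(idx) <- points
  if (present[1]) {
    c1 <- r_off + morph$center[1]
    idx["P_on"] <- idx_of(c1 - k * morph$width[1])
    idx["P_peak"] <- peak_idx(1L)
    idx["P_off"] <- idx_of(c1 + k * morph$width[1])
  }
  if (present[5]) {
    c5 <- r_off + morph$center[5]
    idx["T_on"] <- idx_of(c5 - k * morph$width[5])
    idx["T_peak"] <- peak_idx(5L)
    idx["T_off"] <- idx_of(c5 + k * morph$width[5])
  }
  for (i in 2:4) if (present[i]) idx[nm[i]] <- peak_idx(i)
  qi <- if (present[2]) 2L else 3L
  si <- if (present[4]) 4L else 3L
  idx["QRS_on"] <- idx_of(r_off + morph$center[qi] - k * morph$width[qi])
  idx["QRS_off"] <- idx_of(r_off + morph$center[si] + k * morph$width[si])

  tibble::tibble(
    point = points,
    index = unname(idx),
    t = (unname(idx) - 1L) / fs,
    amp = ifelse(is.na(idx), NA_real_, w[ifelse(is.na(idx), 1L, idx)]),
    absent = is.na(idx))
}
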