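# Preprocessing: Butterworth low-pass filtering and baseline removal.

#' Low-pass Butterworth filter specification
#'
#' @param order Filter order (>= 1).
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist rate.
#' @param zero_phase Apply the filter forward and backward (no group
#'   delay); doubles the attenuation in log scale.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 3L, cutoff = 8, zero_phase = TRUE) {
  assert_scalar_num(order, "order", lower = 1)
  assert_scalar_num(cutoff, "cutoff", lower = 1e-6)
  structure(list(order = as.integer(order), cutoff = cutoff,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# forward(-backward) Butterworth low-pass with reflect padding; the
# workhorse behind every filtering step
apply_butter <- function(x, fs, order, cutoff, zero_phase = TRUE) {
  if (cutoff >= fs / 2) {
    pf_abort("cutoff frequency must be below the Nyquist rate fs/2",
             "pf_invalid_filter")
  }
  n <- length(x)
  if (n <= 3L * order) {
    pf_abort("signal too short for the requested filter order",
             "pf_invalid_filter")
  }
  bt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- min(n - 1L, max(100L, ceiling(3 * fs / cutoff)))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- as.numeric(signal::filter(bt, xp))
  if (zero_phase) y <- rev(as.numeric(signal::filter(bt, rev(y))))
  y[(pad + 1L):(pad + n)]
}

#' Butterworth low-pass filtering
#'
#' Length-preserving low-pass filter with reflect padding at the edges. The
#' pulse channel uses the default 3rd-order, 8 Hz specification; zero-phase
#' (forward-backward) application avoids biasing fiducial timing.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency (Hz).
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
butter_lowpass <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  apply_butter(x, fs, spec$order, spec$cutoff, spec$zero_phase)
}

#' Cubic-spline baseline removal
#'
#' Fits a natural cubic spline through the signal values at the given
#' anchor indices (in practice: the pulse trough points) and subtracts it.
#' The corrected signal is exactly zero at every anchor.
#'
#' @param x Numeric signal.
#' @param anchors Strictly increasing integer indices (>= 4 of them).
#' @return A list with `corrected` and `baseline`, both `length(x)`.
#' @export
spline_baseline_remove <- function(x, anchors) {
  anchors <- as.integer(anchors)
  if (length(anchors) < 4L) {
    pf_abort("at least 4 anchor points are required for a cubic spline",
             "pf_insufficient_anchors")
  }
  if (is.unsorted(anchors, strictly = TRUE) || anchors[1] < 1L ||
      anchors[length(anchors)] > length(x)) {
    pf_abort("anchors must be strictly increasing indices into x",
             "pf_invalid_argument")
  }
  baseline <- stats::spline(x = anchors, y = x[anchors],
                            xout = seq_along(x), method = "natural")$y
  list(corrected = x - baseline, baseline = baseline)
}

#' Two-stage ECG low-pass filtering
#'
#' Stage 1 (40 Hz cutoff) suppresses 50 Hz powerline interference and is
#' used for R-peak detection; stage 2 (20 Hz, applied to stage 1) removes
#' residual EMG-band noise and is used for all other fiducials.
#'
#' @param x Numeric ECG signal.
#' @param fs Sampling frequency (Hz); must exceed 100 Hz.
#' @param order1,order2 Butterworth orders of the two stages.
#' @return A list with `stage1` and `stage2`.
#' @export
ecg_two_stage <- function(x, fs, order1 = 4L, order2 = 4L) {
  if (fs <= 100) pf_abort("fs must exceed 100 Hz", "pf_invalid_argument")
  stage1 <- apply_butter(x, fs, order1, 40, zero_phase = TRUE)
  stage2 <- apply_butter(stage1, fs, order2, 20, zero_phase = TRUE)
  list(stage1 = stage1, stage2 = stage2)
}

#' ECG baseline-wander removal by low-frequency extraction
#'
#' Extracts the baseline with a low-pass filter whose cutoff lies in the
#' 0.2--0.5 Hz band and subtracts it, so `corrected + baseline == x`
#' exactly.
#'
#' @param x Numeric ECG signal.
#' @param fs Sampling frequency (Hz).
#' @param fc Baseline cutoff in Hz (default 0.5), inside `[0.2, 0.5]` unless
#'   `override = TRUE`.
#' @param order Butterworth order of the baseline filter.
#' @param override Allow `fc` outside the standard band.
#' @return A list with `corrected` and `baseline`.
#' @export
ecg_baseline_remove <- function(x, fs, fc = 0.5, order = 3L,
                                override = FALSE) {
  if (!override && (fc < 0.2 || fc > 0.5)) {
    pf_abort("baseline cutoff must lie in [0.2, 0.5] Hz (set override = TRUE to force)",
             "pf_invalid_filter")
  }
  baseline <- apply_butter(x, fs, order, fc, zero_phase = TRUE)
  list(corrected = x - baseline, baseline = baseline)
}

#' Full preprocessing stacks for the two channels
#'
#' `preprocess_ppw()` low-pass filters the pulse channel (3rd order, 8 Hz),
#' detects the cycle troughs and removes baseline drift with a natural
#' cubic spline through them. `preprocess_ecg()` removes baseline wander
#' (0.2--0.5 Hz extraction) and applies the two-stage low-pass.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency (Hz).
#' @return `preprocess_ppw()`: list with `filtered`, `corrected`,
#'   `baseline`, `onsets` (anchor indices). `preprocess_ecg()`: list with
#'   `corrected`, `baseline`, `stage1`, `stage2`.
#' @export
preprocess_ppw <- function(x, fs) {
  filtered <- butter_lowpass(x, fs, filter_spec(3L, 8))
  onsets <- detect_cycles(filtered, fs)
  if (length(onsets) < 4L) {
    pf_abort("fewer than 4 pulse troughs; record unusable", "pf_unusable_record")
  }
  bl <- spline_baseline_remove(filtered, onsets)
  list(filtered = filtered, corrected = bl$corrected,
       baseline = bl$baseline, onsets = onsets)
}

#' @rdname preprocess_ppw
#' @param fc Baseline cutoff (Hz) passed to [ecg_baseline_remove()].
#' @export
preprocess_ecg <- function(x, fs, fc = 0.5) {
  bl <- ecg_baseline_remove(x, fs, fc = fc)
  st <- ecg_two_stage(bl$corrected, fs)
  list(corrected = bl$corrected, baseline = bl$baseline,
       stage1 = st$stage1, stage2 = st$stage2)
}
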