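#' Pulse-wave morphology parameters
#'
#' Describes one noiseless wrist pressure pulse (PPW) cycle as a sum of three
#' positive "bump" components: a log-normal percussion wave (fast systolic
#' upstroke, slower decay) plus Gaussian tidal and dicrotic waves, with an
#' optional inverted-Gaussian notch deepener between the tidal and dicrotic
#' components. The superposition exhibits, in order: onset trough, percussion
#' peak (H1), pre-tidal shoulder (H2), tidal peak (H3), dicrotic notch (H4)
#' and dicrotic peak (H5).
#'
#' @param period Cycle length T in seconds.
#' @param a Length-3 vector of component amplitudes (percussion, tidal,
#'   dicrotic) in arbitrary pressure units; `a[1] > 0`, others `>= 0`.
#' @param mu Length-3 vector of component peak times (seconds from cycle
#'   onset), strictly increasing and inside `(0, period)`.
#' @param s Length-3 vector of component widths (log-sd for the log-normal
#'   percussion bump, Gaussian sd in seconds for the others); all `> 0`.
#' @param notch_depth Depth of the inverted notch bump as a fraction of
#'   `a[1]`; `>= 0`.
#' @param period_sd_ms Beat-to-beat period jitter standard deviation in
#'   milliseconds (used by [synth_record()]).
#'
#' @return An object of class `ppw_morph`.
#' @seealso [synth_ppw_beat()], [ppw_preset()]
#' @export
ppw_morph <- function(period, a, mu, s, notch_depth = 0, period_sd_ms = 0) {
  assert_scalar_num(period, "period", lower = 1e-6)
  if (length(a) != 3L || length(mu) != 3L || length(s) != 3L) {
    pf_abort("`a`, `mu` and `s` must each have length 3", "pf_invalid_morph")
  }
  if (!(a[1] > 0) || any(a[2:3] < 0)) {
    pf_abort("percussion amplitude a[1] must be > 0 and a[2], a[3] >= 0",
             "pf_invalid_morph")
  }
  if (!(0 < mu[1] && mu[1] < mu[2] && mu[2] < mu[3] && mu[3] < period)) {
    pf_abort("component centers must satisfy 0 < mu1 < mu2 < mu3 < period",
             "pf_invalid_morph")
  }
  if (any(s <= 0)) pf_abort("component widths must be > 0", "pf_invalid_morph")
  assert_scalar_num(notch_depth, "notch_depth", lower = 0)
  assert_scalar_num(period_sd_ms, "period_sd_ms", lower = 0)
  structure(
    list(period = period, a = as.numeric(a), mu = as.numeric(mu),
         s = as.numeric(s), notch_depth = notch_depth,
         period_sd_ms = period_sd_ms),
    class = "ppw_morph")
}

#' ECG beat morphology parameters
#'
#' Describes one noiseless ECG beat as a sum of five Gaussian waves
#' (P, Q, R, S, T; Q and S negative) positioned relative to the R peak.
#'
#' @param rr RR period in seconds.
#' @param amp Named or ordered length-5 vector of wave amplitudes
#'   (P, Q, R, S, T) in millivolt-scale arbitrary units; Q and S should be
#'   negative, and `amp["R"]` must exceed `|Q|` and `|S|`.
#' @param center Length-5 vector of wave-center offsets from the R peak in
#'   seconds (P and Q negative, R zero, S and T positive), strictly
#'   increasing.
#' @param width Length-5 vector of Gaussian standard deviations in seconds.
#' @param rr_sd_ms Beat-to-beat RR jitter standard deviation (ms).
#'
#' @return An object of class `ecg_morph`.
#' @seealso [synth_ecg_beat()], [ecg_preset()]
#' @export
ecg_morph <- function(rr, amp, center, width, rr_sd_ms = 0) {
  assert_scalar_num(rr, "rr", lower = 1e-6)
  if (length(amp) != 5L || length(center) != 5L || length(width) != 5L) {
    pf_abort("`amp`, `center` and `width` must each have length 5",
             "pf_invalid_morph")
  }
  amp <- as.numeric(amp); center <- as.numeric(center); width <- as.numeric(width)
  if (is.unsorted(center, strictly = TRUE)) {
    pf_abort("wave centers must be strictly ordered P < Q < R < S < T",
             "pf_invalid_morph")
  }
  if (!(amp[3] > abs(amp[2]) && amp[3] > abs(amp[4]))) {
    pf_abort("R amplitude must exceed |Q| and |S|", "pf_invalid_morph")
  }
  if (any(width <= 0)) pf_abort("wave widths must be > 0", "pf_invalid_morph")
  structure(
    list(rr = rr, amp = amp, center = center, width = width,
         rr_sd_ms = rr_sd_ms),
    class = "ecg_morph")
}

#' Noise specification for synthetic records
#'
#' The additive disturbances emulated on top of the noiseless two-channel
#' signal: respiratory baseline drift (a slow sinusoid, 0.2--0.35 Hz),
#' 50 Hz powerline interference, band-limited 20--40 Hz EMG noise, and
#' broadband white noise. Amplitudes are in channel units (the percussion
#' peak and the R peak are both ~1 by default), applied per channel via
#' the `ppw_*` / `ecg_*` scale factors.
#'
#' @param resp_hz Respiratory drift frequency in Hz (0.2--0.35).
#' @param resp_amp Drift amplitude.
#' @param mains_hz Powerline frequency in Hz.
#' @param mains_amp Powerline amplitude.
#' @param emg_amp Standard deviation of the 20--40 Hz band-limited noise.
#' @param white_sd Standard deviation of white noise.
#' @param ppw_scale,ecg_scale Per-channel multipliers applied to
#'   (`resp_amp`, `mains_amp`, `emg_amp`, `white_sd`). The default routes
#'   drift predominantly to the pressure channel and powerline/EMG noise to
#'   the ECG channel, matching how the two sensors pick up interference.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(resp_hz = 0.25, resp_amp = 0, mains_hz = 50,
                       mains_amp = 0, emg_amp = 0, white_sd = 0,
                       ppw_scale = c(resp = 1, mains = 0.2, emg = 0.1, white = 1),
                       ecg_scale = c(resp = 0.5, mains = 1, emg = 1, white = 1)) {
  assert_scalar_num(resp_hz, "resp_hz", lower = 0.05, upper = 1)
  for (nm in c("resp_amp", "mains_amp", "emg_amp", "white_sd")) {
    assert_scalar_num(get(nm), nm, lower = 0)
  }
  structure(
    list(resp_hz = resp_hz, resp_amp = resp_amp, mains_hz = mains_hz,
         mains_amp = mains_amp, emg_amp = emg_amp, white_sd = white_sd,
         ppw_scale = ppw_scale, ecg_scale = ecg_scale),
    class = "noise_spec")
}

#' Named noise profiles
#'
#' `"clean"` is noiseless; `"clinical"` emulates a resting bedside
#' acquisition: respiratory drift at 0.25 Hz with amplitude 0.3 (30% of the
#' percussion peak on the pressure channel), 50 Hz powerline at 10% of the R
#' peak, EMG-band noise at 5%, and a small white-noise floor.
#'
#' @param profile `"clean"` or `"clinical"`.
#' @return A [noise_spec()].
#' @export
noise_profile <- function(profile = c("clean", "clinical")) {
  profile <- match.arg(profile)
  switch(profile,
    clean = noise_spec(),
    clinical = noise_spec(resp_hz = 0.25, resp_amp = 0.30, mains_amp = 0.10,
                          emg_amp = 0.05, white_sd = 0.01))
}
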