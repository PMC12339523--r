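# Synthetic two-channel (PPW + ECG) records and cohorts.

# draw one subject's demographics for a group; pre-truncation locations are
# solved so the truncated means equal the published group means
draw_demographics <- function(group) {
  d <- pf_demo_reference()[group, ]
  draw <- function(mean, sd, lo, hi) {
    mu <- truncnorm_solve_mu(mean, sd, lo, hi)
    rtruncnorm(1L, mu, sd, lo, hi)
  }
  list(sex = if (stats::runif(1) < d$p_male) "male" else "female",
       age = draw(d$age_mean, d$age_sd, 20, 75),
       bmi = draw(d$bmi_mean, d$bmi_sd, 15, 40),
       sbp = draw(d$sbp_mean, d$sbp_sd, 85, 200),
       dbp = draw(d$dbp_mean, d$dbp_sd, 45, 120))
}

# subject-level mean pulse period (s), drawn from the group's published
# period distribution (median on the table value, spread from the IQR),
# truncated to a plausible resting band; the RR and pulse periods coincide
# in a phase-locked two-channel record
draw_period <- function(group) {
  ref <- pf_ppw_reference()
  r <- ref[ref$feature == "T" & ref$group == group, ]
  sd <- (r$q3 - r$q1) / 1.349                # IQR -> sd under normality
  mu <- truncnorm_solve_mu_median(r$median, sd, 0.62, 1.30)
  rtruncnorm(1L, mu, sd, 0.62, 1.30)
}

# band-limited 20-40 Hz noise with unit sd (EMG surrogate)
emg_noise <- function(n, fs) {
  x <- stats::rnorm(n + 2000L)
  bp <- signal::butter(4, c(20, 40) / (fs / 2), type = "pass")
  y <- as.numeric(signal::filter(bp, x))[-seq_len(2000L)]
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Synthesize one two-channel subject record
#'
#' Generates a synchronized wrist-pulse (PPW) + ECG record for one subject
#' of the given study group: beats are concatenated with Gaussian
#' beat-to-beat period jitter (sd = the group's pulse-SDNN median), the two
#' channels are phase-locked (each pulse onset trails its R peak by a fixed
#' pulse-transit delay), noise is added per [noise_spec()], demographics are
#' drawn from the group's published moments, and exact ground-truth
#' fiducials are stored for every complete beat.
#'
#' @param group Group label in 1..4 (healthy, CHD, CHD+HTN, CHD+HTN+DM).
#' @param seed Integer seed; identical seeds give bit-identical records.
#' @param duration Record length in seconds.
#' @param fs Sampling frequency in Hz.
#' @param noise A [noise_spec()]; default clean (noiseless).
#' @param id Subject identifier string.
#' @param subject_jitter Relative between-subject variation of morphology
#'   amplitudes/timings (log-normal sd); 0 disables it.
#' @param transit_delay Pulse-transit delay from R peak to pulse onset (s).
#' @param period_sd_ms Beat-to-beat period jitter sd in ms; `NULL` uses the
#'   group's pulse-SDNN median, 0 gives perfectly periodic beats.
#' @param period Subject mean period in seconds; `NULL` draws it from the
#'   group's period distribution.
#'
#' @return A `pf_record`: list with `id`, `fs`, `duration`, `group`,
#'   `demographics`, `signal` (tibble `t`, `ppw`, `ecg`), and `truth`
#'   (list of per-beat fiducial tibbles `ppw`, `ecg`, plus `onsets` and
#'   `r_peaks` in absolute sample indices).
#' @export
synth_record <- function(group, seed, duration = 60, fs = 1100,
                         noise = noise_spec(), id = NULL,
                         subject_jitter = 0.04, transit_delay = 0.2,
                         period_sd_ms = NULL, period = NULL) {
  if (!is.numeric(group) || length(group) != 1L || !group %in% 1:4) {
    pf_abort("unknown group label (must be 1, 2, 3 or 4)", "pf_unknown_group")
  }
  assert_scalar_num(duration, "duration", lower = 3)
  assert_scalar_num(fs, "fs", lower = 50)
  stopifnot(inherits(noise, "noise_spec"))
  group <- as.integer(group)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  demo <- draw_demographics(group)
  rr_mean <- period %||% draw_period(group)
  hr <- 60 / rr_mean
  sd_ms <- period_sd_ms %||% pf_period_sd_ms[group]

  # subject-level morphology variation around the group preset
  jit <- function(x, rel = subject_jitter) x * exp(stats::rnorm(length(x), 0, rel))
  pt <- pf_ppw_preset_table()[group, ]
  pmorph <- ppw_morph(period = rr_mean,
                      a = c(1, jit(pt$a2), jit(pt$a3)),
                      mu = sort(c(jit(pt$m1, subject_jitter / 2),
                                  jit(pt$mu2, subject_jitter / 2),
                                  jit(pt$mu3, subject_jitter / 2))),
                      s = c(jit(pt$s1), jit(pt$s2), jit(pt$s3)),
                      notch_depth = pt$notch,
                      period_sd_ms = pf_period_sd_ms[group])
  emorph0 <- ecg_preset(group, rr = rr_mean)
  emorph <- ecg_morph(rr = rr_mean,
                      amp = emorph0$amp * exp(stats::rnorm(5, 0, subject_jitter)),
                      center = emorph0$center, width = emorph0$width,
                      rr_sd_ms = emorph0$rr_sd_ms)

  n <- round(fs * duration)
  t_all <- (seq_len(n) - 1) / fs

  # beat-to-beat period series (shared by the two phase-locked channels)
  sd_s <- sd_ms / 1000
  n_beats <- ceiling(duration / max(rr_mean - 3 * sd_s, 0.62)) + 4L
  periods <- pmax(0.62, pmin(1.40, rr_mean + stats::rnorm(n_beats, 0, sd_s)))
  starts <- c(0, cumsum(periods))[seq_len(n_beats)]
  r_off <- 0.26
  r_times <- starts + r_off

  # ECG channel: superpose every beat's five Gaussian components
  ecg <- numeric(n)
  for (b in seq_len(n_beats)) {
    lo <- max(1L, floor((starts[b]) * fs) + 1L)
    hi <- min(n, ceiling((starts[b] + periods[b]) * fs) + 1L)
    if (lo > n) break
    seg <- lo:hi
    ecg[seg] <- ecg[seg] + ecg_beat_values(t_all[seg] - starts[b], emorph, r_off)
  }

  # PPW channel: pulse onsets trail R peaks by the transit delay; a
  # phantom lead-in beat fills the head of the record
  onset_times <- r_times + transit_delay
  ppw <- numeric(n)
  pm_b <- function(period) {
    m <- pmorph; m$period <- period; m
  }
  lead_start <- onset_times[1] - periods[1]
  seg <- seq_len(min(n, max(1L, floor(onset_times[1] * fs))))
  ppw[seg] <- ppw_cycle_values(t_all[seg] - lead_start, pm_b(periods[1]))
  for (b in seq_len(n_beats - 1L)) {
    lo <- floor(onset_times[b] * fs) + 1L
    hi <- min(n, floor(onset_times[b + 1L] * fs))
    if (lo > n) break
    seg <- lo:hi
    ppw[seg] <- ppw_cycle_values(t_all[seg] - onset_times[b],
                                 pm_b(onset_times[b + 1L] - onset_times[b]))
  }

  # ground truth for every complete beat inside the record
  ppw_truth <- list(); ecg_truth <- list()
  onsets_idx <- integer(); r_idx <- integer()
  for (b in seq_len(n_beats - 1L)) {
    lo <- floor(onset_times[b] * fs) + 1L
    hi <- min(n, floor(onset_times[b + 1L] * fs))
    if (lo >= 1L && hi <= n && (hi - lo) / fs > 0.5 &&
        onset_times[b + 1L] * fs <= n) {
      seg <- ppw[lo:hi]
      tr <- ppw_core_to_tibble(locate_ppw_core(seg, fs, strict = FALSE),
                               seg, fs, offset = lo - 1L)
      tr$beat <- b
      ppw_truth[[length(ppw_truth) + 1L]] <- tr
      onsets_idx <- c(onsets_idx, lo)
    }
    beat_lo <- floor(starts[b] * fs) + 1L
    beat_hi <- floor((starts[b] + periods[b]) * fs)
    if (beat_lo >= 1L && beat_hi <= n) {
      nb <- beat_hi - beat_lo + 1L
      wseg <- ecg[beat_lo:beat_hi]
      etr <- ecg_beat_truth(emorph, fs, r_off, nb, wseg)
      etr$beat <- b
      etr$index <- etr$index + beat_lo - 1L
      etr$t <- etr$t + (beat_lo - 1L) / fs
      ecg_truth[[length(ecg_truth) + 1L]] <- etr
      r_idx <- c(r_idx, etr$index[etr$point == "R"])
    }
  }

  # additive noise
  if (noise$resp_amp > 0) {
    ph <- stats::runif(1, 0, 2 * pi)
    drift <- sin(2 * pi * noise$resp_hz * t_all + ph)
    ppw <- ppw + noise$ppw_scale[["resp"]] * noise$resp_amp * drift
    ecg <- ecg + noise$ecg_scale[["resp"]] * noise$resp_amp * drift
  }
  if (noise$mains_amp > 0) {
    ph <- stats::runif(1, 0, 2 * pi)
    mains <- sin(2 * pi * noise$mains_hz * t_all + ph)
    ppw <- ppw + noise$ppw_scale[["mains"]] * noise$mains_amp * mains
    ecg <- ecg + noise$ecg_scale[["mains"]] * noise$mains_amp * mains
  }
  if (noise$emg_amp > 0) {
    e <- emg_noise(n, fs)
    ppw <- ppw + noise$ppw_scale[["emg"]] * noise$emg_amp * e
    ecg <- ecg + noise$ecg_scale[["emg"]] * noise$emg_amp * emg_noise(n, fs)
  }
  if (noise$white_sd > 0) {
    ppw <- ppw + noise$ppw_scale[["white"]] * stats::rnorm(n, 0, noise$white_sd)
    ecg <- ecg + noise$ecg_scale[["white"]] * stats::rnorm(n, 0, noise$white_sd)
  }

  structure(
    list(id = id %||% sprintf("g%d-s%d", group, as.integer(seed)),
         fs = fs, duration = duration, group = group, demographics = demo,
         signal = tibble::tibble(t = t_all, ppw = ppw, ecg = ecg),
         truth = list(ppw = dplyr::bind_rows(ppw_truth),
                      ecg = dplyr::bind_rows(ecg_truth),
                      onsets = onsets_idx, r_peaks = r_idx),
         meta = list(seed = as.integer(seed), hr = hr, rr_mean = rr_mean,
                     transit_delay = transit_delay)),
    class = "pf_record")
}

#' @export
print.pf_record <- function(x, ...) {
  cat(sprintf("<pf_record %s> group %d, %.0f s @ %.0f Hz (%d samples/channel)\n",
              x$id, x$group, x$duration, x$fs, nrow(x$signal)))
  cat(sprintf("  demographics: %s, age %.0f, BMI %.1f, BP %.0f/%.0f\n",
              x$demographics$sex, x$demographics$age, x$demographics$bmi,
              x$demographics$sbp, x$demographics$dbp))
  invisible(x)
}

#' Synthesize a cohort of records
#'
#' Generates `sum(counts)` subjects with the given per-group sizes. Each
#' subject's record derives its seed from the master seed by counter
#' splitting, so a subject's record does not depend on cohort composition.
#'
#' @param counts Integer vector of length 4: subjects per group.
#' @param seed Master seed.
#' @param duration,fs,noise,subject_jitter Passed to [synth_record()].
#' @return A tibble with one row per subject: `id`, `group` (factor),
#'   demographics columns, and a `record` list-column of `pf_record`s.
#' @export
synth_cohort <- function(counts, seed, duration = 60, fs = 1100,
                         noise = noise_spec(), subject_jitter = 0.04) {
  if (length(counts) != 4L || any(counts < 0)) {
    pf_abort("`counts` must be 4 non-negative integers", "pf_invalid_argument")
  }
  rows <- list()
  for (g in 1:4) {
    for (i in seq_len(counts[g])) {
      rec <- synth_record(g, seed = subject_seed(seed, g, i),
                          duration = duration, fs = fs, noise = noise,
                          id = sprintf("g%d-%03d", g, i),
                          subject_jitter = subject_jitter)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = rec$id, group = g, sex = rec$demographics$sex,
        age = rec$demographics$age, bmi = rec$demographics$bmi,
        sbp = rec$demographics$sbp, dbp = rec$demographics$dbp,
        record = list(rec))
    }
  }
  out <- if (length(rows) == 0L) {
    tibble::tibble(id = character(), group = integer(), sex = character(),
                   age = numeric(), bmi = numeric(), sbp = numeric(),
                   dbp = numeric(), record = list())
  } else dplyr::bind_rows(rows)
  out$group <- factor(out$group, levels = 1:4)
  out
}

#' Write / read one record as CSV + JSON sidecars
#'
#' The signal goes to `<stem>.csv` (columns `t,ppw,ecg`), subject metadata
#' to `<stem>.json`, and ground truth (when present) to `<stem>_truth.json`.
#'
#' @param record A `pf_record`.
#' @param stem Output path stem (no extension).
#' @return `write_record()` returns `stem` invisibly; `read_record()`
#'   returns a `pf_record` (without ground truth unless the sidecar exists).
#' @export
write_record <- function(record, stem) {
  stopifnot(inherits(record, "pf_record"))
  readr::write_csv(record$signal, paste0(stem, ".csv"))
  meta <- c(list(id = record$id, fs = record$fs, duration = record$duration,
                 group = record$group), record$demographics)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(record$truth) && nrow(record$truth$ppw) > 0) {
    jsonlite::write_json(
      list(ppw = record$truth$ppw, ecg = record$truth$ecg,
           onsets = record$truth$onsets, r_peaks = record$truth$r_peaks),
      paste0(stem, "_truth.json"), digits = NA)
  }
  invisible(stem)
}

#' @rdname write_record
#' @export
read_record <- function(stem) {
  sig <- readr::read_csv(paste0(stem, ".csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  truth <- NULL
  tf <- paste0(stem, "_truth.json")
  if (file.exists(tf)) {
    tr <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- list(ppw = tibble::as_tibble(tr$ppw),
                  ecg = tibble::as_tibble(tr$ecg),
                  onsets = tr$onsets, r_peaks = tr$r_peaks)
  }
  structure(
    list(id = meta$id, fs = meta$fs, duration = meta$duration,
         group = meta$group,
         demographics = meta[c("sex", "age", "bmi", "sbp", "dbp")],
         signal = tibble::as_tibble(sig), truth = truth, meta = list()),
    class = "pf_record")
}
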