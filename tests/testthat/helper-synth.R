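# Shared fixtures, all generated in code.

fs_std <- 1100

# pulse train with an explicit beat-period sequence (s); gentle entry/exit
# ramps keep the onset troughs unambiguous
make_ppw_train <- function(periods, group = 1, fs = fs_std, pad = 1) {
  morph <- ppw_preset(group)
  npad <- round(pad * fs)
  lead <- seq(0.02, 0, length.out = npad)
  beats <- unlist(lapply(periods, function(p) {
    m <- morph; m$period <- p
    t <- (seq_len(round(p * fs)) - 1) / fs
    pulsefuse:::ppw_cycle_values(t, m)
  }))
  # one terminal beat so the last onset of interest has a following cycle
  m <- morph; m$period <- periods[length(periods)]
  t <- (seq_len(round(m$period * fs)) - 1) / fs
  term <- pulsefuse:::ppw_cycle_values(t, m)
  tail <- seq(0, 0.02, length.out = npad)
  c(lead, beats, term, tail)
}

# ECG train with an explicit RR sequence (s)
make_ecg_train <- function(rrs, group = 1, fs = fs_std, pad = 1) {
  morph <- ecg_preset(group)
  npad <- round(pad * fs)
  starts <- pad + c(0, cumsum(rrs))
  total <- pad + sum(rrs) + rrs[length(rrs)] + pad
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (s0 in starts) x <- x + pulsefuse:::ecg_beat_values(t - s0, morph, 0.26)
  x
}

# well-separated 4-class Gaussian blobs
make_blobs <- function(n_per = 50, p = 2, delta = 6, seed = 1) {
  set.seed(seed)
  y <- factor(rep(1:4, each = n_per))
  centers <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE) * delta
  X <- matrix(rnorm(4 * n_per * p), ncol = p)
  X[, 1] <- X[, 1] + centers[as.integer(y), 1]
  X[, 2] <- X[, 2] + centers[as.integer(y), 2]
  colnames(X) <- paste0("f", seq_len(p))
  data.frame(X, group = y)
}

# planted-signal data: few informative features among pure noise
make_planted <- function(seed, n_per = 25, p_inf = 4, p_noise = 36,
                         delta = 1.0) {
  set.seed(seed)
  y <- factor(rep(1:4, each = n_per))
  centers <- matrix(rnorm(4 * p_inf), 4, p_inf) * delta
  X <- centers[as.integer(y), ] + matrix(rnorm(4 * n_per * p_inf), ncol = p_inf)
  X <- cbind(X, matrix(rnorm(4 * n_per * p_noise), ncol = p_noise))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  data.frame(X, group = y)
}

# amplitude ratio of a pure tone after an operation
tone_ratio <- function(freq, fs, n_sec, fun) {
  t <- (seq_len(round(n_sec * fs)) - 1) / fs
  x <- sin(2 * pi * freq * t)
  y <- fun(x)
  core <- seq(round(length(x) * 0.25), round(length(x) * 0.75))
  sqrt(mean(y[core]^2) / mean(x[core]^2))
}
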