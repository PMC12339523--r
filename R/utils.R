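# Internal helpers shared across modules.

# stop() with a classed condition so tests can assert on error class
pf_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "pulsefuse_error"))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    pf_abort(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
             "pf_invalid_argument")
  }
  invisible(x)
}

# sample standard deviation / RMS of successive differences, both in the
# units of `x`; the HRV workhorses (SDNN / RMSSD and their pulse analogues)
sdnn <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

rmssd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  sqrt(mean(diff(x)^2))
}

# indices of strict local maxima / minima of a numeric vector
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  d <- diff(x)
  which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
}

local_minima <- function(x) local_maxima(-x)

# trapezoidal integral of y over uniformly sampled grid with spacing dt
trapz_area <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * sum((y[-1] + y[-n]) / 2)
}

# total time (s) a cycle spends above `level`, with linear interpolation at
# the crossings; used for the pulse widths W1/W2
time_above_level <- function(y, level, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  above <- y > level
  total <- 0
  for (i in seq_len(n - 1L)) {
    y0 <- y[i]; y1 <- y[i + 1L]
    if (above[i] && above[i + 1L]) {
      total <- total + dt
    } else if (above[i] != above[i + 1L]) {
      frac <- (level - y0) / (y1 - y0)
      total <- total + dt * (if (above[i]) frac else 1 - frac)
    }
  }
  total
}

# deterministic per-subject seed derived from a master seed by counter
# splitting; keeps individual records invariant to cohort membership order
subject_seed <- function(master_seed, group, index) {
  (as.integer(master_seed) %% 100003L) * 20011L +
    as.integer(group) * 4999L + as.integer(index) * 7L
}

# mean of a normal(mu, sd) truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# draw from a truncated normal by rejection (vectorised, bounded retries)
rtruncnorm <- function(n, mu, sd, lo, hi) {
  out <- stats::rnorm(n, mu, sd)
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mu, sd)
    bad <- which(out < lo | out > hi)
    tries <- tries + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(mu, lo), hi)
  out
}

# location parameter mu* such that a normal(mu*, sd) truncated to [lo, hi]
# has mean `target`; used to keep cohort demographics on their table values
# despite plausibility truncation
truncnorm_solve_mu <- function(target, sd, lo, hi) {
  f <- function(mu) truncnorm_mean(mu, sd, lo, hi) - target
  stats::uniroot(f, lower = target - 3 * sd, upper = target + 3 * sd)$root
}

# median of a normal(mu, sd) truncated to [lo, hi]
truncnorm_median <- function(mu, sd, lo, hi) {
  a <- stats::pnorm((lo - mu) / sd)
  b <- stats::pnorm((hi - mu) / sd)
  mu + sd * stats::qnorm((a + b) / 2)
}

# location parameter such that the truncated median equals `target`
truncnorm_solve_mu_median <- function(target, sd, lo, hi) {
  f <- function(mu) truncnorm_median(mu, sd, lo, hi) - target
  stats::uniroot(f, lower = target - 3 * sd, upper = target + 3 * sd)$root
}

# column-median imputation for occasional missing feature values (e.g. a
# subject whose dicrotic-notch features could not be measured); modeling
# code cannot digest NAs
impute_median <- function(X) {
  for (j in seq_along(X)) {
    x <- X[[j]]
    if (anyNA(x)) {
      m <- stats::median(x, na.rm = TRUE)
      if (!is.finite(m)) m <- 0
      x[is.na(x)] <- m
      X[[j]] <- x
    }
  }
  X
}
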