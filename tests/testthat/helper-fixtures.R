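# Shared fixtures: small, fast configurations used across the module tests.
# Signal sizes are scaled down relative to the full study conditions where the
# property under test does not depend on the problem size.

# quick IRASA configuration for short test signals
quick_cfg <- function(n_h = 10L, frange = c(1, 30), n_sub = 15L, frac = 0.9) {
  irasa_config(srate = 250, frange = frange,
               hset = seq(1.05, 1.5, length.out = n_h),
               n_subsegments = n_sub, subsegment_fraction = frac)
}

# low-overlap PSD variant: short subsegments give real Welch averaging, so
# spectra are smooth enough for sharp fixed-point checks
smooth_cfg <- function(n_h = 10L, frange = c(1, 30)) {
  irasa_config(srate = 250, frange = frange,
               hset = seq(1.05, 1.5, length.out = n_h),
               n_subsegments = 15L, subsegment_fraction = 0.1)
}

# independent log-log least-squares slope on the raw one-segment periodogram
# (the oracle for power-law exponent recovery; deliberately avoids the
# package's PSD and fitting code)
oracle_periodogram_beta <- function(x, fs, frange = c(1, 30)) {
  n <- length(x)
  p <- Mod(stats::fft(x))[2:(n %/% 2)]^2
  f <- fs * seq_len(n %/% 2 - 1) / n
  keep <- f >= frange[1] & f <= frange[2]
  # bin-average onto a log grid to tame the chi-square scatter
  lf <- log(f[keep]); lp <- log(p[keep])
  cuts <- cut(lf, breaks = 40)
  mf <- tapply(lf, cuts, mean); mp <- tapply(lp, cuts, mean)
  ok <- !is.na(mf)
  -unname(stats::coef(stats::lm(mp[ok] ~ mf[ok]))[2])
}

# exact piecewise power-law spectrum on a dense grid (amplitude-continuous
# at the breakpoint)
piecewise_spectrum <- function(beta_lo, beta_hi, f_break = 13,
                               freqs = seq(1, 30, by = 0.01)) {
  p <- ifelse(freqs < f_break,
              freqs^(-beta_lo),
              f_break^(-beta_lo) * (freqs / f_break)^(-beta_hi))
  list(freqs = freqs, power = p)
}

# brute-force Benjamini-Hochberg step-up: scan ranks from the largest down,
# find the largest k with p_(k) <= k/m * alpha, reject the k smallest
bh_oracle_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in m:1) {
    if (ps[i] <= i / m * alpha) { k <- i; break }
  }
  rej <- logical(m)
  if (k > 0L) rej[o[seq_len(k)]] <- TRUE
  rej
}

# tiny two-group cohort spec for pipeline-level tests
tiny_spec <- function(seed = 1L, n_samples = 2048L, n_per_group = 5L,
                      group_effects = list()) {
  synthetic_spec(
    n_samples = n_samples, n_per_group = n_per_group,
    oscillations = data.frame(center = 10, amplitude = 0.2, bandwidth = 2),
    group_effects = group_effects, seed = seed)
}
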