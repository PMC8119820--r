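#' Canonical EEG frequency bands
#'
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30 Hz. Band edges are half-open
#' `[low, high)` except the beta band, which is closed at 30 Hz, so every
#' frequency bin in 1-30 Hz belongs to exactly one band (13 Hz belongs to
#' beta) and the four band powers partition the 1-30 Hz integral.
#'
#' @return named list of `c(low, high)` pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

# Least-squares line on prepared log-log points; beta is the negative slope.
powerlaw_fit_points <- function(logf, logp) {
  n <- length(logf)
  xbar <- mean(logf); ybar <- mean(logp)
  sxx <- sum((logf - xbar)^2)
  slope <- sum((logf - xbar) * (logp - ybar)) / sxx
  intercept <- ybar - slope * xbar
  rss <- sum((logp - intercept - slope * logf)^2)
  list(beta = -slope, intercept = intercept, rss = rss, n_points = n)
}

# Resample (log f, log P) to an even grid on the log-frequency axis:
# 20 points per octave (2 per octave-tenth), linear interpolation of
# log-power versus log-frequency. Non-positive powers are excluded first
# (possible in fractal estimates); their count is reported via attribute.
log_even_points <- function(freqs, power, fit_range) {
  sel <- freqs >= fit_range[1] - 1e-9 & freqs <= fit_range[2] + 1e-9
  f <- freqs[sel]; p <- power[sel]
  n_dropped <- sum(p <= 0)
  if (n_dropped > 0) {
    message(sprintf("fit_powerlaw: excluded %d non-positive power value(s) in [%g, %g] Hz",
                    n_dropped, fit_range[1], fit_range[2]))
    f <- f[p > 0]; p <- p[p > 0]
  }
  if (length(f) < 5L) {
    stop_invalid(sprintf(
      "degenerate fit: fewer than 5 positive power values in [%g, %g] Hz",
      fit_range[1], fit_range[2]))
  }
  n_pts <- max(5L, ceiling(20 * log2(fit_range[2] / fit_range[1])) + 1L)
  grid <- exp(seq(log(fit_range[1]), log(fit_range[2]), length.out = n_pts))
  grid <- grid[grid >= min(f) & grid <= max(f)]
  out <- stats::approx(log(f), log(p), xout = log(grid))
  structure(list(logf = out$x, logp = out$y), n_dropped = n_dropped)
}

#' Fit a power law to a spectrum segment
#'
#' Fits `log P = intercept - beta * log f` by least squares on points
#' resampled to be evenly spaced in log-frequency (20 points per octave,
#' linear interpolation of log-power), which removes the linear-grid
#' overrepresentation of high frequencies. `beta` is the negative fitted
#' slope. Non-positive power values inside the range (possible after fractal
#' estimation) are excluded with a message; fewer than 5 usable values is an
#' error.
#'
#' @param freqs frequency grid in Hz.
#' @param power spectral power at `freqs`.
#' @param fit_range `c(low, high)` in Hz.
#' @return list with `beta`, `intercept` (log power at 1 Hz), `rss`,
#'   `n_points`.
#' @export
fit_powerlaw <- function(freqs, power, fit_range) {
  if (length(fit_range) != 2L || fit_range[1] <= 0 || fit_range[1] >= fit_range[2]) {
    stop_invalid("fit_range must be c(low, high) with 0 < low < high")
  }
  pts <- log_even_points(freqs, power, fit_range)
  powerlaw_fit_points(pts$logf, pts$logp)
}

#' Bimodal spectral-exponent fit with goodness-of-fit comparison
#'
#' Fits the fractal spectrum with (a) two independent power laws below and
#' above the breakpoint (`beta_lo` on `[full_range[1], f_break]`, `beta_hi`
#' above it) and (b) a single power law over the full range, all evaluated on
#' the same log-evenly resampled points (grid built once over `full_range`;
#' points at or below `f_break` feed the low fit). The bimodal/unimodal
#' residual sums of squares are compared with an F test
#' (`F = ((rss_uni - rss_bi)/2) / (rss_bi/(n - 4))`; the breakpoint is fixed,
#' not estimated, so the bimodal model spends 4 parameters against 2).
#'
#' @param freqs frequency grid in Hz.
#' @param fractal_power fractal spectrum at `freqs`.
#' @param f_break breakpoint in Hz (default 13).
#' @param full_range full fitting range (default `c(1, 30)`).
#' @return object of class `bimodal_fit`: `beta_lo`, `beta_hi`,
#'   `delta_beta = beta_hi - beta_lo`, `beta_uni`, `rss_bi`, `rss_uni`,
#'   `f_gof`, `p_gof`, `n_points`.
#' @export
fit_bimodal <- function(freqs, fractal_power, f_break = 13,
                        full_range = c(1, 30)) {
  if (f_break <= full_range[1] || f_break >= full_range[2]) {
    stop_invalid("f_break must lie strictly inside full_range")
  }
  pts <- log_even_points(freqs, fractal_power, full_range)
  lo <- pts$logf <= log(f_break) + 1e-12
  if (sum(lo) < 5L || sum(!lo) < 5L) {
    stop_invalid("degenerate fit: fewer than 5 points in a sub-range")
  }
  fit_lo <- powerlaw_fit_points(pts$logf[lo], pts$logp[lo])
  fit_hi <- powerlaw_fit_points(pts$logf[!lo], pts$logp[!lo])
  fit_uni <- powerlaw_fit_points(pts$logf, pts$logp)
  rss_bi <- fit_lo$rss + fit_hi$rss
  rss_uni <- fit_uni$rss
  n <- length(pts$logf)
  df_bi <- n - 4L
  if (rss_uni <= .Machine$double.eps * n) {
    f_gof <- 0; p_gof <- 1          # both models exact: no evidence either way
  } else {
    f_gof <- ((rss_uni - rss_bi) / 2) / (rss_bi / df_bi)
    p_gof <- stats::pf(f_gof, 2, df_bi, lower.tail = FALSE)
  }
  structure(
    list(beta_lo = fit_lo$beta, beta_hi = fit_hi$beta,
         delta_beta = fit_hi$beta - fit_lo$beta, beta_uni = fit_uni$beta,
         rss_bi = rss_bi, rss_uni = rss_uni, f_gof = f_gof, p_gof = p_gof,
         n_points = n),
    class = "bimodal_fit"
  )
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat(sprintf(
    "<bimodal_fit> beta_lo %.3f, beta_hi %.3f (delta %.3f); beta_uni %.3f; GoF F = %.2f, p = %.3g\n",
    x$beta_lo, x$beta_hi, x$delta_beta, x$beta_uni, x$f_gof, x$p_gof))
  invisible(x)
}

#' Band-limited power
#'
#' Sum of power-density bins whose frequency falls in `[low, high)` (set
#' `closed_upper = TRUE` to include the upper edge, as for the beta band at
#' 30 Hz), times the bin width, i.e. the integral of the spectrum over the
#' band. With half-open bands the four canonical bands partition the
#' 1-30 Hz integral exactly. Negative bins (oscillatory spectra) are
#' retained, not clipped.
#'
#' @param freqs uniform frequency grid in Hz.
#' @param power power density at `freqs` (may be negative for oscillatory
#'   components).
#' @param band `c(low, high)` in Hz.
#' @param closed_upper include bins at exactly `high` (default FALSE).
#' @return scalar band-limited power (normalized power for standardized
#'   signals).
#' @export
band_limited_power <- function(freqs, power, band, closed_upper = FALSE) {
  if (length(band) != 2L || band[1] >= band[2]) {
    stop_invalid("band must be c(low, high) with low < high")
  }
  sel <- freqs >= band[1] - 1e-9 &
    (if (closed_upper) freqs <= band[2] + 1e-9 else freqs < band[2] - 1e-9)
  if (!any(sel)) {
    stop_invalid(sprintf("degenerate band [%g, %g] Hz: no frequency bins",
                         band[1], band[2]))
  }
  df <- if (length(freqs) > 1L) freqs[2L] - freqs[1L] else 1
  sum(power[sel]) * df
}

#' Band-limited power of all components of a decomposition
#'
#' @param decomp a `spectral_decomposition` from [irasa_separate()].
#' @param bands named list of bands (default [eeg_bands()]); the last band is
#'   closed at its upper edge.
#' @return data.frame with columns `band`, `component`, `blp`.
#' @export
decomposition_blp <- function(decomp, bands = eeg_bands()) {
  stopifnot(inherits(decomp, "spectral_decomposition"))
  comp <- c("mixed", "fractal", "oscillatory")
  out <- expand.grid(band = names(bands), component = comp,
                     stringsAsFactors = FALSE)
  out$blp <- mapply(function(b, cm) {
    band_limited_power(decomp$freqs, decomp[[cm]], bands[[b]],
                       closed_upper = b == names(bands)[length(bands)])
  }, out$band, out$component)
  out
}
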