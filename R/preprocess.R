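#' @importFrom signal butter
NULL

# Steady-state initial filter delays (direct form II transposed), the
# Gustafsson-style initialization that makes the filter start in steady state
# for a step input. Mirrors the standard lfilter_zi construction.
iir_steady_state <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1L) return(numeric(0))
  # companion matrix of a, transposed
  A <- rbind(-a[-1], cbind(diag(n - 2L), numeric(n - 2L)))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - t(A), B)
}

# Plain R DF2T recursion; only used for the run-in prefix -- the bulk of each
# signal goes through the C-level recursive filter in filter_fast().
.filter_df2t <- function(b, a, x, z) {
  n <- length(b)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2L) {
      for (j in 1:(n - 2L)) z[j] <- b[j + 1L] * xi + z[j + 1L] - a[j + 1L] * yi
    }
    z[n - 1L] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# design cache: butter() and the steady-state solve are deterministic in
# (order, low, high, fs), and cohort generation calls them thousands of times
.filter_cache <- new.env(parent = emptyenv())

butter_design <- function(fs, low, high, order) {
  key <- paste(fs, low, high, order, sep = "|")
  des <- .filter_cache[[key]]
  if (is.null(des)) {
    flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
    des <- list(b = flt$b, a = flt$a, zi = iir_steady_state(flt$b, flt$a))
    .filter_cache[[key]] <- des
  }
  des
}

# Zero-phase (forward-backward) Butterworth band-pass with odd-reflection
# padding and steady-state initialization, so edge transients and DC offsets
# are handled exactly (constant input maps to ~0 at double precision).
zero_phase_filter <- function(x, fs, low, high, order = 5L) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop_invalid("cutoffs must satisfy 0 < low < high < Nyquist")
  }
  des <- butter_design(fs, low, high, order)
  b <- des$b; a <- des$a
  nfilt <- max(length(a), length(b))
  npad <- max(3L * (nfilt - 1L), 3L * order)
  n <- length(x)
  if (npad >= n) stop_invalid("signal too short for the requested filter order")
  ext <- c(2 * x[1] - x[(npad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  zi <- des$zi
  y <- filter_fast(b, a, ext, zi * ext[1])
  y <- rev(filter_fast(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1L):(npad + n)]
}

# Vectorized IIR via stats::filter: FIR part by convolution, recursive part by
# the C recursive filter; initial conditions imposed by running-in a short
# prefix with the plain-R DF2T recursion and splicing.
filter_fast <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  run_in <- min(length(x), 5L * n)
  head_y <- .filter_df2t(b, a, x[seq_len(run_in)], c(zi, numeric(0)))
  if (run_in == length(x)) return(head_y)
  # remaining samples: recursive filter seeded with the exact previous outputs
  v <- stats::filter(c(x[(run_in - n + 2L):length(x)]), b, method = "convolution",
                     sides = 1L)
  v <- v[-seq_len(n - 1L)]
  tail_y <- stats::filter(v, -a[-1], method = "recursive",
                          init = rev(head_y[(run_in - n + 2L):run_in]))
  c(head_y, as.numeric(tail_y))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a zero-phase (forward-backward) Butterworth
#' band-pass of the given order. Forward-backward application squares the
#' magnitude response and cancels the phase, so the group delay is zero and
#' the output has the same length as the input. Edges are handled by
#' odd-reflection padding (at least 3x the filter length) with steady-state
#' initial conditions.
#'
#' @param rec an [recording()].
#' @param low,high cutoff frequencies in Hz (defaults 0.5 and 45).
#' @param order Butterworth design order (default 5; the band-pass has twice
#'   that many poles).
#' @return the filtered recording.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 45, order = 5L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high)) stop_invalid("need 0 < low < high")
  if (high >= rec$fs / 2) {
    stop_invalid(sprintf("upper cutoff %g Hz is not below Nyquist (%g Hz)",
                         high, rec$fs / 2))
  }
  rec$data <- t(apply(rec$data, 1L, zero_phase_filter,
                      fs = rec$fs, low = low, high = high, order = order))
  rownames(rec$data) <- rec$labels
  rec
}

#' Standardize each channel to zero mean and unit variance
#'
#' Uses the population variance (divide by n); with 2^14-sample segments the
#' difference from n-1 is immaterial but the convention is fixed so that the
#' integrated PSD of a standardized channel equals 1 by construction.
#'
#' @param rec an [recording()].
#' @return the standardized recording.
#' @export
standardize <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  for (i in seq_len(nrow(rec$data))) {
    rec$data[i, ] <- standardize_vector(rec$data[i, ], rec$labels[i])
  }
  rec
}

#' Surface-Laplacian (current source density) transform
#'
#' Reference-free CSD estimates by the spherical-spline method of Perrin et
#' al.: the scalp potential at each time point is interpolated by a spherical
#' spline of order `m` (Legendre series truncated at `n_legendre` terms,
#' ridge regularizer `lambda`), and the surface Laplacian of the spline is
#' evaluated at the electrodes. Adding any constant to all channels at a time
#' point leaves the output unchanged (reference invariance).
#'
#' @param rec an [recording()] with valid unit-sphere positions for every
#'   channel.
#' @param m spline flexibility order (default 4).
#' @param n_legendre number of Legendre terms (default 50).
#' @param lambda ridge regularizer added to the diagonal of the G matrix
#'   (default 1e-5).
#' @return the transformed recording (CSD units).
#' @export
csd_transform <- function(rec, m = 4L, n_legendre = 50L, lambda = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"))
  pos <- rec$positions
  if (anyNA(pos)) {
    stop_invalid("missing electrode position(s) for: ",
                 paste(rec$labels[apply(is.na(pos), 1L, any)], collapse = ", "))
  }
  nch <- nrow(pos)
  if (nch < 4L) stop_invalid("CSD needs at least 4 channels with positions")
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  if (any(cosang[upper.tri(cosang)] > 1 - 1e-10)) {
    stop_invalid("duplicate electrode positions")
  }
  GH <- csd_gh_matrices(cosang, m, n_legendre)
  M <- rbind(cbind(GH$G + diag(lambda, nch), rep(1, nch)),
             c(rep(1, nch), 0))
  rhs <- rbind(rec$data, 0)
  sol <- solve(M, rhs)               # rows 1..nch: spline coefficients c
  rec$data <- GH$H %*% sol[seq_len(nch), , drop = FALSE]
  rownames(rec$data) <- rec$labels
  rec
}

# G and H kernel matrices of the spherical spline (Legendre series over the
# matrix of inter-electrode cosine angles, computed by the three-term
# recurrence).
csd_gh_matrices <- function(cosang, m, n_legendre) {
  G <- matrix(0, nrow(cosang), ncol(cosang))
  H <- G
  Pprev <- matrix(1, nrow(cosang), ncol(cosang))  # P_0
  Pcur <- cosang                                   # P_1
  for (l in seq_len(n_legendre)) {
    if (l > 1L) {
      Pnew <- ((2 * l - 1) * cosang * Pcur - (l - 1) * Pprev) / l
      Pprev <- Pcur
      Pcur <- Pnew
    }
    ll1 <- l * (l + 1)
    G <- G + (2 * l + 1) / ll1^m * Pcur
    H <- H + (2 * l + 1) / ll1^(m - 1) * Pcur
  }
  list(G = G / (4 * pi), H = -H / (4 * pi))
}

#' Augmented Dickey-Fuller stationarity screen
#'
#' Runs an ADF unit-root test on every channel (regression with constant;
#' lag order chosen by AIC up to `floor((n-1)^(1/3))`); the null hypothesis
#' is a unit root, so `p < alpha` supports stationarity. Non-stationary
#' channels trigger a warning, not a hard stop: the spectral pipeline is
#' advisory-gated, matching common practice for resting-state segments.
#'
#' @param rec an [recording()] with at least 50 samples per channel.
#' @param alpha significance level for the stationarity call (default .05).
#' @return data.frame with columns `channel`, `statistic`, `lag`, `p`,
#'   `stationary`.
#' @export
check_stationarity <- function(rec, alpha = 0.05) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) < 50L) stop_invalid("need at least 50 samples per channel")
  res <- lapply(seq_len(nrow(rec$data)), function(i) {
    a <- adf_test(rec$data[i, ], label = rec$labels[i])
    data.frame(channel = rec$labels[i], statistic = a$statistic, lag = a$lag,
               p = a$p, stationary = a$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (any(!out$stationary)) {
    warning("non-stationary channel(s) at alpha = ", alpha, ": ",
            paste(out$channel[!out$stationary], collapse = ", "),
            call. = FALSE)
  }
  out
}

# ADF regression: diff(x)_t ~ const + x_{t-1} + lagged diffs; lag by AIC on a
# common effective sample; tau statistic mapped to p by interpolating the
# standard tau_mu quantile table (clamped to [0.01, 0.99] as is conventional).
adf_test <- function(x, label = "signal") {
  n <- length(x)
  if (stats::var(x) == 0) {
    stop_invalid(sprintf("degenerate input: channel '%s' is constant", label))
  }
  kmax <- max(0L, floor((n - 1)^(1 / 3)))
  dx <- diff(x)
  nd <- length(dx)
  aic <- rep(NA_real_, kmax + 1L)
  # common sample: rows (kmax+1) .. nd of dx
  idx <- (kmax + 1L):nd
  y <- dx[idx]
  for (k in 0:kmax) {
    X <- cbind(1, x[idx])            # constant + lagged level
    if (k > 0L) {
      lagmat <- sapply(seq_len(k), function(j) dx[idx - j])
      X <- cbind(X, lagmat)
    }
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    aic[k + 1L] <- length(y) * log(rss / length(y)) + 2 * (k + 2L)
  }
  k <- which.min(aic) - 1L
  idx <- (k + 1L):nd
  X <- cbind(1, x[idx])
  if (k > 0L) X <- cbind(X, sapply(seq_len(k), function(j) dx[idx - j]))
  fit <- stats::lm.fit(X, dx[idx])
  rss <- sum(fit$residuals^2)
  dfree <- length(idx) - ncol(X)
  sigma2 <- rss / dfree
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  stat <- fit$coefficients[2L] / se
  # asymptotic tau_mu quantiles (Dickey-Fuller distribution, constant model)
  tab_p <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  tab_q <- c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)
  p <- stats::approx(tab_q, tab_p, xout = stat, rule = 2L)$y
  list(statistic = unname(stat), lag = k, p = p)
}
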