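# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_invalid(sprintf("`%s` must be positive (got %g)", name, x))
  }
  invisible(x)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# Symmetric Hanning taper (as used for FFT windowing of finite segments).
hanning_taper <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

# Remove per-column linear trend (least squares) from a matrix of segments.
detrend_columns <- function(m) {
  n <- nrow(m)
  t0 <- seq_len(n) - (n + 1) / 2          # centered time axis
  ss <- sum(t0^2)
  means <- colMeans(m)
  slopes <- as.vector(crossprod(m, t0)) / ss
  m - rep(means, each = n) - outer(t0, slopes)
}

# Population standardization (divide by n, not n - 1): fixed convention so the
# integrated PSD of a standardized channel is 1 by construction.
standardize_vector <- function(x, label = "signal") {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (v <= 0 || !is.finite(v)) {
    stop_invalid(sprintf("degenerate input: channel '%s' has zero variance", label))
  }
  (x - mu) / sqrt(v)
}
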