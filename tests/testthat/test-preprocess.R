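make_rec <- function(data, fs = 250, labels = NULL) {
  if (is.null(labels)) labels <- channels_1020()[seq_len(nrow(data))]
  recording(data, fs, labels)
}

test_that("zero-phase band-pass removes DC and passes the mid-band", {
  fs <- 250; n <- 8192
  dc <- make_rec(matrix(5, 1, n), fs, "Cz")
  out <- bandpass_filter(dc)
  expect_lt(max(abs(out$data)), 5 * 1e-6)

  t <- seq_len(n) / fs
  s10 <- make_rec(matrix(sin(2 * pi * 10 * t), 1, n), fs, "Cz")
  y <- bandpass_filter(s10)$data[1, ]
  mid <- 1000:7000                       # steady-state portion
  amp <- sqrt(2 * mean(y[mid]^2))
  expect_lt(abs(amp - 1), 0.01)
})

test_that("stop-band attenuation matches the closed-form Butterworth response", {
  # oracle: analytic magnitude response of the digital order-5 Butterworth
  # band-pass (bilinear design, band edges prewarped), squared for the
  # forward-backward application
  fs <- 250; n <- 16384
  W <- function(f) tan(pi * f / fs)
  w1 <- W(0.5); w2 <- W(45)
  H2 <- function(f) {
    x <- (W(f)^2 - w1 * w2) / (W(f) * (w2 - w1))
    1 / (1 + x^(2 * 5))
  }
  t <- seq_len(n) / fs
  y <- bandpass_filter(make_rec(matrix(sin(2 * pi * 60 * t), 1, n), fs, "Cz"))$data[1, ]
  mid <- 2000:14000
  amp <- sqrt(2 * mean(y[mid]^2))
  expect_lt(abs(amp - H2(60)) / H2(60), 0.05)
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- make_rec(matrix(rnorm(1000), 1), 250, "Cz")
  expect_error(bandpass_filter(rec, 0.5, 130), "Nyquist")
})

test_that("standardize gives exact zero mean / unit variance and errors on flat channels", {
  rec <- make_rec(matrix(rnorm(2 * 4096, 5, 3), 2), 250)
  out <- standardize(rec)
  expect_true(all(abs(rowMeans(out$data)) < 1e-12))
  expect_true(all(abs(apply(out$data, 1, function(v) mean(v^2)) - 1) < 1e-12))
  # idempotent
  out2 <- standardize(out)
  expect_lt(max(abs(out2$data - out$data)), 1e-12)

  flat <- make_rec(rbind(rnorm(100), rep(1, 100)), 250, c("C3", "C4"))
  expect_error(standardize(flat), "C4")
})

test_that("integrated PSD of standardized white noise is ~1", {
  set.seed(5)
  x <- standardize(make_rec(matrix(rnorm(16384), 1), 250, "Cz"))$data[1, ]
  ps <- estimate_mixed_psd(x, irasa_config(frange = c(0.001, 124.99)))
  integral <- sum(ps$mixed) * (ps$freqs[2] - ps$freqs[1])
  expect_lt(abs(integral - 1), 0.05)
})

test_that("CSD is reference-free and annihilates spatially uniform activity", {
  set.seed(8)
  rec <- standardize(make_rec(matrix(rnorm(19 * 512), 19), 250))
  out <- csd_transform(rec)
  # adding a (time-varying) offset to all channels changes nothing
  shifted <- rec
  shifted$data <- rec$data + rep(rnorm(512, 10, 5), each = 19)
  out2 <- csd_transform(shifted)
  expect_lt(max(abs(out$data - out2$data)), 1e-8)
  # spatially uniform sample -> zero CSD
  unif <- rec
  unif$data <- matrix(rep(rnorm(512), each = 19), 19)
  expect_lt(max(abs(csd_transform(unif)$data)), 1e-8)
})

test_that("CSD matches an independent Legendre-series oracle on an impulse pattern", {
  skip_if_not_installed("pracma")
  labels <- channels_1020()
  pos <- montage_1020()
  P <- as.matrix(pos[, c("x", "y", "z")])
  # 20 Legendre terms: pracma::legendre is accurate there (it degrades by
  # degree ~50), and the series is already well converged at m = 4
  nch <- 19L; m <- 4; nleg <- 20L; lambda <- 1e-5
  cosang <- tcrossprod(P); cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  # oracle: explicit Legendre-polynomial summation via pracma::legendre
  g <- matrix(0, nch, nch); h <- matrix(0, nch, nch)
  for (l in seq_len(nleg)) {
    Pl <- apply(cosang, c(1, 2), function(v) pracma::legendre(l, v)[1])
    g <- g + (2 * l + 1) / (l * (l + 1))^m * Pl
    h <- h - (2 * l + 1) / (l * (l + 1))^(m - 1) * Pl
  }
  g <- g / (4 * pi); h <- h / (4 * pi)
  v <- c(1, rep(0, nch - 1))             # unit impulse on the first channel
  M <- rbind(cbind(g + diag(lambda, nch), rep(1, nch)), c(rep(1, nch), 0))
  sol <- solve(M, c(v, 0))
  oracle <- as.vector(h %*% sol[1:nch])

  rec <- recording(matrix(v, nch, 1), 250, labels)
  got <- csd_transform(rec, m = m, n_legendre = nleg, lambda = lambda)$data[, 1]
  expect_equal(unname(got), oracle, tolerance = 1e-10)
})

test_that("CSD input validation", {
  rec <- recording(matrix(rnorm(3 * 64), 3), 250, c("C3", "C4", "Cz"))
  expect_error(csd_transform(rec), "at least 4")
  dup <- recording(matrix(rnorm(4 * 64), 4), 250, c("C3", "C4", "Cz", "Pz"),
                   positions = rbind(c(1, 0, 0), c(1, 0, 0),
                                     c(0, 1, 0), c(0, 0, 1)))
  expect_error(csd_transform(dup), "duplicate")
})

test_that("ADF screen rejects the unit root for white noise, not for random walks", {
  set.seed(99)
  rej_wn <- rej_rw <- logical(100)
  for (i in 1:100) {
    wn <- rnorm(1024)
    rw <- cumsum(rnorm(1024))
    rej_wn[i] <- fractalEEG:::adf_test(wn)$p < 0.05
    rej_rw[i] <- fractalEEG:::adf_test(rw)$p < 0.05
  }
  expect_gte(mean(rej_wn), 0.95)
  expect_lt(mean(rej_rw), 0.5)
})

test_that("stationarity screen warns on non-stationary channels and errors on constants", {
  set.seed(4)
  rec <- recording(rbind(rnorm(512), cumsum(rnorm(512))), 250, c("C3", "C4"))
  expect_warning(res <- check_stationarity(rec), "C4")
  expect_true(res$stationary[1])
  expect_false(res$stationary[2])
  const <- recording(rbind(rnorm(512), rep(2, 512)), 250, c("C3", "C4"))
  expect_error(check_stationarity(const), "constant")
})
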