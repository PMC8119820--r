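test_that("exact power laws are fitted exactly", {
  f <- seq(0.5, 40, by = 0.005)
  fit1 <- fit_powerlaw(f, f^(-1), c(1, 30))
  expect_lt(abs(fit1$beta - 1), 1e-9)
  fit0 <- fit_powerlaw(f, rep(3.7, length(f)), c(1, 30))
  expect_lt(abs(fit0$beta), 1e-9)
  expect_lt(fit0$rss, 1e-18)
})

test_that("beta is recovered from fractal spectra of synthetic noise", {
  betas <- vapply(1:8, function(s) {
    x <- generate_scalefree_noise(16384, 250, 1.5, 1.5, seed = 880 + s)
    dec <- irasa_separate(x, quick_cfg())
    fit_powerlaw(dec$freqs, dec$fractal, c(1, 30))$beta
  }, 0)
  expect_lt(abs(mean(betas) - 1.5), 0.1)
})

test_that("non-positive powers are excluded; degenerate ranges error", {
  f <- seq(1, 30, by = 0.1)
  p <- f^(-1)
  p[5:10] <- -1
  expect_message(fit <- fit_powerlaw(f, p, c(1, 30)), "excluded 6")
  expect_lt(abs(fit$beta - 1), 0.05)
  expect_error(suppressMessages(fit_powerlaw(f, -(f^(-1)), c(1, 30))),
               "degenerate fit")
  expect_error(fit_powerlaw(f, p, c(31, 40)), "degenerate fit")
})

test_that("bimodal fit on an exact piecewise spectrum recovers both slopes", {
  sp <- piecewise_spectrum(1, 2)
  fit <- fit_bimodal(sp$freqs, sp$power)
  expect_lt(abs(fit$beta_lo - 1), 0.02)
  expect_lt(abs(fit$beta_hi - 2), 0.02)
  expect_lt(abs(fit$delta_beta - 1), 0.02)
  expect_identical(fit$delta_beta, fit$beta_hi - fit$beta_lo)
  expect_lt(fit$p_gof, 0.05)
  expect_lte(fit$rss_bi, fit$rss_uni)
})

test_that("unimodal noisy spectra yield small delta-beta and non-significant GoF", {
  set.seed(61)
  ok_db <- ok_p <- logical(50)
  # generate on the fitter's own log-even grid so the spectral noise is iid
  # on the fitted points and the GoF F test is exact under the null
  n_pts <- ceiling(20 * log2(30)) + 1
  f <- exp(seq(log(1), log(30), length.out = n_pts))
  for (i in 1:50) {
    # multiplicative spectral noise around a single power law (the scale of
    # smoothed fractal-estimate scatter; see the methods vignette)
    p <- f^(-1.5) * exp(rnorm(length(f), 0, 0.02))
    fit <- fit_bimodal(f, p)
    ok_db[i] <- abs(fit$delta_beta) < 0.05
    ok_p[i] <- fit$p_gof > 0.05
  }
  expect_gte(mean(ok_db & ok_p), 0.9)
})

test_that("nested-model dominance holds on shared points for noisy inputs", {
  set.seed(77)
  f <- seq(1, 30, by = 0.05)
  for (i in 1:20) {
    p <- f^(-runif(1, 0.5, 2)) * exp(rnorm(length(f), 0, 0.3))
    fit <- fit_bimodal(f, p)
    expect_lte(fit$rss_bi, fit$rss_uni + 1e-12)
  }
})

test_that("band power integrates concentrated and uniform spectra correctly", {
  f <- seq(1, 30, by = 0.01)
  p <- ifelse(f >= 2 & f <= 3, 5, 0)
  total <- sum(p) * 0.01
  expect_equal(band_limited_power(f, p, c(1, 4)), total, tolerance = 1e-9)
  expect_equal(band_limited_power(f, p, c(4, 8)), 0)
  # uniform spectrum: band powers in the ratio of the band widths
  u <- rep(1, length(f))
  blps <- vapply(eeg_bands(), function(b)
    band_limited_power(f, u, b, closed_upper = b[2] == 30), 0)
  expect_equal(unname(blps / blps[1]), c(3, 4, 5, 17) / 3, tolerance = 0.01)
  expect_error(band_limited_power(f, p, c(40, 50)), "degenerate band")
})

test_that("the four bands partition the 1-30 Hz integral of any decomposition", {
  x <- generate_scalefree_noise(4096, 250, 1, 1.5, seed = 5)
  dec <- irasa_separate(x, quick_cfg(n_h = 5))
  tab <- decomposition_blp(dec)
  df <- dec$freqs[2] - dec$freqs[1]
  for (cm in c("mixed", "fractal", "oscillatory")) {
    full <- sum(dec[[cm]]) * df
    expect_equal(sum(tab$blp[tab$component == cm]), full, tolerance = 1e-9)
  }
  # component additivity propagates to every band
  wide <- reshape(tab, idvar = "band", timevar = "component", direction = "wide")
  expect_equal(wide$blp.mixed, wide$blp.fractal + wide$blp.oscillatory,
               tolerance = 1e-12)
})

test_that("band power is scale-equivariant and beta scale-invariant", {
  f <- seq(1, 30, by = 0.01)
  p <- f^(-1.2)
  c0 <- 7.3
  expect_equal(band_limited_power(f, c0 * p, c(4, 8)),
               c0 * band_limited_power(f, p, c(4, 8)))
  expect_equal(fit_powerlaw(f, c0 * p, c(1, 30))$beta,
               fit_powerlaw(f, p, c(1, 30))$beta, tolerance = 1e-12)
})

test_that("group-mean exponent maps reproduce the frontal/occipital topology", {
  # frontal channels get steeper beta_lo, occipital steeper beta_hi by
  # construction; check the estimated group means preserve that ordering
  spec <- synthetic_spec(n_samples = 4096, n_per_group = 3, seed = 10,
                         oscillations = data.frame(center = 10, amplitude = 0.15,
                                                   bandwidth = 2))
  recs <- generate_cohort(spec)[1:3]
  cfg <- quick_cfg(n_h = 8)
  fits <- lapply(recs, function(r) {
    vapply(seq_len(19), function(ci) {
      dec <- irasa_separate(r$data[ci, ], cfg)
      fb <- fit_bimodal(dec$freqs, dec$fractal)
      c(fb$beta_lo, fb$beta_hi)
    }, numeric(2))
  })
  avg <- Reduce(`+`, fits) / length(fits)
  frontal <- channels_1020() %in% c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz")
  occ <- channels_1020() %in% c("O1", "O2", "T5", "T6")
  expect_gt(mean(avg[1, frontal]), mean(avg[1, occ]))   # beta_lo higher frontally
  expect_gt(mean(avg[2, occ]), mean(avg[2, frontal]))   # beta_hi higher occipitally
})
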