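test_that("routing is a pure function of the three booleans (8-case truth table)", {
  route <- fractalEEG:::route_test
  expect_identical(route(TRUE, TRUE, TRUE), "t")
  expect_identical(route(TRUE, TRUE, FALSE), "welch_t")
  # any non-normal group forces Mann-Whitney regardless of the variance test
  for (ev in c(TRUE, FALSE)) {
    expect_identical(route(FALSE, TRUE, ev), "mann_whitney")
    expect_identical(route(TRUE, FALSE, ev), "mann_whitney")
    expect_identical(route(FALSE, FALSE, ev), "mann_whitney")
  }
})

test_that("identical normal samples give the pooled t with p = 1", {
  set.seed(1)
  x <- rnorm(14)
  res <- compare_groups(x, x)
  expect_identical(res$test_used, "t")
  expect_equal(res$p_raw, 1)
})

test_that("a large mean shift is detected through the parametric branch", {
  set.seed(2)
  x <- rnorm(14, 0, 1); y <- rnorm(14, 5, 1)
  res <- compare_groups(x, y)
  expect_true(res$test_used %in% c("t", "welch_t"))
  expect_lt(res$p_raw, 0.001)
})

test_that("non-normal samples are routed to Mann-Whitney", {
  # routing cross-checked with an independent run of the normality test
  set.seed(3)
  x <- rnorm(14)
  repeat {
    y <- rexp(14)^3
    if (nortest::lillie.test(y)$p.value < 0.05) break
  }
  expect_gte(nortest::lillie.test(x)$p.value, 0.05)
  res <- compare_groups(x, y)
  expect_identical(res$test_used, "mann_whitney")
  expect_error(compare_groups(rnorm(4), rnorm(10)), "at least 5")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  res <- bh_fdr(c(.01, .02, .03, .04, .05), alpha = .05)
  expect_true(all(res$rejected))
  expect_false(any(bh_fdr(c(.2, .6, .9), .05)$rejected))
  expect_true(bh_fdr(.04, .05)$rejected)
  expect_false(bh_fdr(.06, .05)$rejected)
  # property: every random p-vector of length 1..12 matches the oracle
  set.seed(10)
  for (rep in 1:60) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    got <- bh_fdr(p, .05)
    expect_identical(got$rejected, bh_oracle_reject(p, .05))
    # monotone in rank
    expect_true(all(diff(got$p_adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("delta-beta one-sample tests route by normality and handle degeneracy", {
  expect_identical(delta_beta_test(rep(0, 14)),
                   list(test_used = "degenerate", p_raw = 1))
  set.seed(4)
  res <- delta_beta_test(rnorm(14, 1, 0.1))
  expect_identical(res$test_used, "t")
  expect_lt(res$p_raw, 0.001)
  set.seed(6)
  repeat {
    z <- exp(rnorm(14, 0, 2)); z <- z - median(z)
    if (nortest::lillie.test(z)$p.value < 0.05) break
  }
  expect_identical(delta_beta_test(z)$test_used, "wilcoxon")
})

test_that("ANCOVA absorbs covariate-mediated effects but detects orthogonal ones", {
  set.seed(11)
  absorbed <- orthogonal <- logical(50)
  group <- rep(c("A", "B"), each = 14)
  for (i in 1:50) {
    frac <- rnorm(28) + ifelse(group == "B", 1, 0)
    absorbed[i] <- ancova_group_effect(frac, frac, group) > 0.05
    frac0 <- rnorm(28)
    mix <- frac0 + ifelse(group == "B", 1, 0) + rnorm(28, 0, 0.3)
    orthogonal[i] <- ancova_group_effect(mix, frac0, group) < 0.05
  }
  expect_gte(mean(absorbed), 0.9)
  expect_gt(mean(orthogonal), 0.5)
})

test_that("constant covariate reduces ANCOVA to the pooled two-sample t test", {
  set.seed(12)
  x <- rnorm(28); g <- rep(c("A", "B"), each = 14)
  expect_warning(p <- ancova_group_effect(x, rep(1, 28), g), "constant covariate")
  expect_equal(p, stats::t.test(x ~ g, var.equal = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("effect size and power match definitions and a Monte-Carlo oracle", {
  x <- c(0.5, 1, 1.5); y <- c(-0.5, 0, 0.5)   # means 1 vs 0, pooled sd 0.5
  ep <- effect_size_and_power(x, y)
  expect_equal(ep$d, 2)
  # identical groups: d = 0 and power equals the test size
  ep0 <- effect_size_and_power(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ep0$d, 0)
  expect_equal(ep0$power, 0.05, tolerance = 1e-12)
  expect_error(effect_size_and_power(rep(1, 5), rep(1, 5)), "pooled")

  # Monte-Carlo oracle: rejection rate of the two-sample t at d = 1, n = 14
  set.seed(13)
  nrep <- 1e5
  xs <- matrix(rnorm(14 * nrep, 1), 14)
  ys <- matrix(rnorm(14 * nrep, 0), 14)
  mx <- colMeans(xs); my <- colMeans(ys)
  vx <- colSums((xs - rep(mx, each = 14))^2) / 13
  vy <- colSums((ys - rep(my, each = 14))^2) / 13
  tstat <- (mx - my) / sqrt((vx + vy) / 14)
  mc_power <- mean(abs(tstat) > qt(0.975, 26))
  # package value at an observed d of exactly 1 (constructed samples)
  xd <- seq(-1, 1, length.out = 14); xd <- xd / sqrt(var(xd) * 13 / 13)
  theo_power <- effect_size_and_power(xd + 1, xd)$power
  expect_lt(abs(mc_power - theo_power), 0.01)
})

test_that("sliding windows declare a stationary full-segment slope representative", {
  cfg <- quick_cfg(n_h = 8, n_sub = 5)
  x <- generate_scalefree_noise(16384, 250, 1, 1, seed = 55)
  rep10 <- sliding_window_validation(x, cfg, window_s = 10, n_windows = 40L)
  row <- rep10[rep10$exponent == "beta_lo", ]
  expect_true(row$inside_band)
  expect_gt(row$p_representative, 0.05)
  expect_error(sliding_window_validation(x, cfg, window_s = 120),
               "exceeds the signal")
})

test_that("a mid-record slope switch breaks representativeness", {
  cfg <- quick_cfg(n_h = 8, n_sub = 5)
  hits <- vapply(1:7, function(s) {
    x <- c(generate_scalefree_noise(8192, 250, 2, 2, seed = 70 + s),
           generate_scalefree_noise(8192, 250, 0.5, 0.5, seed = 170 + s))
    # windows confined to the first (steep, beta = 2) half; the full-segment
    # spectrum is a mixture dominated at high frequency by the shallow half,
    # so its slope falls below the steep-half window distribution
    rep10 <- sliding_window_validation(x, cfg, window_s = 10, n_windows = 12L)
    !rep10$inside_band[rep10$exponent == "beta_lo"]
  }, TRUE)
  expect_gt(mean(hits), 0.5)
})

test_that("family-wise comparison table adjusts within band x component families", {
  set.seed(20)
  tab <- expand.grid(subject = sprintf("S%02d", 1:10),
                     band = c("delta", "theta"), component = c("mixed", "fractal"),
                     channel = c("C3", "C4", "Cz"), stringsAsFactors = FALSE)
  tab$group <- ifelse(as.integer(sub("S", "", tab$subject)) <= 5, "G1", "G2")
  tab$value <- rnorm(nrow(tab))
  # inject a large effect in one cell family
  sel <- tab$band == "delta" & tab$component == "fractal" & tab$channel == "C3"
  tab$value[sel & tab$group == "G1"] <- tab$value[sel & tab$group == "G1"] + 8
  res <- group_comparison_table(tab)
  expect_identical(nrow(res), 12L)
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  hit <- res$band == "delta" & res$component == "fractal" & res$channel == "C3"
  expect_true(res$significant[hit])
  expect_gt(res$d[hit], 2)
})
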