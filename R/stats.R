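#' @importFrom nortest lillie.test
#' @importFrom car Anova
NULL

# Pure routing rule: normality of both groups decides parametric vs
# Mann-Whitney; the variance F test then picks pooled vs Welch t.
route_test <- function(normal_x, normal_y, equal_var) {
  if (!normal_x || !normal_y) return("mann_whitney")
  if (equal_var) "t" else "welch_t"
}

# Lilliefors normality call with the degenerate-sample guard the routing
# needs; constant samples are treated as non-normal (Mann-Whitney route).
is_normal_lilliefors <- function(x, alpha) {
  if (stats::sd(x) == 0) return(FALSE)
  stats::sd(x) > 0 && nortest::lillie.test(x)$p.value >= alpha
}

#' Two-group comparison with normality-routed test selection
#'
#' Implements the branching rule of the analysis pipeline: Lilliefors tests
#' on both groups first; if either rejects normality at `alpha` the groups
#' are compared with a Mann-Whitney U test; otherwise an F test of variance
#' equality at `alpha` routes to the pooled two-sample t test (equal
#' variances) or the Welch-corrected t test (unequal). All p values are
#' two-sided.
#'
#' @param x,y numeric samples (each `n >= 5`, the domain of the Lilliefors
#'   p approximation).
#' @param alpha level used by the intermediate Lilliefors and variance F
#'   tests (default .05).
#' @return list with `test_used` (`"t"`, `"welch_t"` or `"mann_whitney"`)
#'   and `p_raw`.
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  if (length(x) < 5L || length(y) < 5L) {
    stop_invalid("each group needs at least 5 observations (normality routing undefined below that)")
  }
  norm_x <- is_normal_lilliefors(x, alpha)
  norm_y <- is_normal_lilliefors(y, alpha)
  equal_var <- if (norm_x && norm_y) {
    stats::var.test(x, y)$p.value >= alpha
  } else NA
  test_used <- route_test(norm_x, norm_y, isTRUE(equal_var))
  p_raw <- switch(
    test_used,
    t = stats::t.test(x, y, var.equal = TRUE)$p.value,
    welch_t = stats::t.test(x, y, var.equal = FALSE)$p.value,
    mann_whitney = suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))$p.value
  )
  list(test_used = test_used, p_raw = p_raw)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH procedure: adjusted p values are monotone non-decreasing in
#' raw-p rank and the rejection mask is `p_adj <= alpha`.
#'
#' @param p_values vector of raw p values in `[0, 1]`.
#' @param alpha FDR level (default .05).
#' @return list with `p_adj` and logical `rejected` (both in input order).
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_invalid("all p values must lie in [0, 1]")
  }
  p_adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adj = p_adj, rejected = p_adj <= alpha)
}

#' One-sample test of spectral bimodality (delta-beta against zero)
#'
#' Tests whether per-subject `delta_beta = beta_hi - beta_lo` values differ
#' from zero: a one-sample t test when the Lilliefors test accepts normality
#' at `alpha`, otherwise a one-sample Wilcoxon signed-rank test; two-sided.
#' An all-zero sample is flagged degenerate and returns p = 1.
#'
#' @param delta_betas per-subject delta-beta values (`n >= 5`).
#' @param alpha level of the Lilliefors routing test (default .05).
#' @return list with `test_used` (`"t"`, `"wilcoxon"` or `"degenerate"`)
#'   and `p_raw`.
#' @export
delta_beta_test <- function(delta_betas, alpha = 0.05) {
  if (length(delta_betas) < 5L) stop_invalid("need at least 5 observations")
  if (all(delta_betas == 0)) {
    return(list(test_used = "degenerate", p_raw = 1))
  }
  if (is_normal_lilliefors(delta_betas, alpha)) {
    list(test_used = "t",
         p_raw = stats::t.test(delta_betas, mu = 0)$p.value)
  } else {
    list(test_used = "wilcoxon",
         p_raw = suppressWarnings(
           stats::wilcox.test(delta_betas, mu = 0, exact = FALSE))$p.value)
  }
}

#' ANCOVA: group effect on mixed band power with the fractal power as covariate
#'
#' Fits `mixed ~ group + fractal` and reports the type-II p value of the
#' group term, quantifying whether a group difference in mixed band-limited
#' power survives adjustment for the fractal component. A constant covariate
#' degrades the model to the plain one-way comparison (pooled t test),
#' with a warning.
#'
#' @param mixed_blp per-subject mixed band power.
#' @param fractal_blp per-subject fractal band power (covariate).
#' @param group group labels (two levels, `>= 3` subjects each).
#' @return p value for the group term.
#' @export
ancova_group_effect <- function(mixed_blp, fractal_blp, group) {
  group <- factor(group)
  if (nlevels(group) != 2L || any(table(group) < 3L)) {
    stop_invalid("need two groups with at least 3 subjects each")
  }
  if (stats::var(fractal_blp) == 0) {
    warning("constant covariate: falling back to the plain group comparison",
            call. = FALSE)
    fit <- stats::lm(mixed_blp ~ group)
    return(stats::anova(fit)[["Pr(>F)"]][1L])
  }
  fit <- stats::lm(mixed_blp ~ group + fractal_blp)
  rss_full <- sum(stats::residuals(fit)^2)
  if (rss_full <= 1e-12 * sum((mixed_blp - mean(mixed_blp))^2)) {
    # covariate (plus group) reproduces the response exactly; the group term
    # adds nothing testable beyond the covariate
    rss_red <- sum(stats::residuals(stats::lm(mixed_blp ~ fractal_blp))^2)
    return(if (rss_red - rss_full <= rss_red * 1e-9 ||
               rss_red <= .Machine$double.eps) 1 else 0)
  }
  tab <- car::Anova(fit, type = 2)
  tab["group", "Pr(>F)"]
}

#' Cohen's d and post-hoc power of the two-sample t test
#'
#' `d` is the mean difference over the pooled standard deviation; power is
#' the probability that the two-sided two-sample t test at level `alpha`
#' rejects, evaluated at the observed effect size and group sizes
#' (noncentral-t formula). At d = 0 the power equals the test size `alpha`.
#'
#' @param x,y numeric samples (`n >= 2` each).
#' @param alpha test level (default .05).
#' @return list with `d` and `power`.
#' @export
effect_size_and_power <- function(x, y, alpha = 0.05) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop_invalid("need at least 2 observations per group")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop_invalid("degenerate input: zero pooled standard deviation")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- stats::qt(1 - alpha / 2, df)
  power <- stats::pt(-crit, df, ncp) + stats::pt(crit, df, ncp,
                                                 lower.tail = FALSE)
  list(d = d, power = power)
}

#' Sliding-window representativeness of the full-segment spectral slope
#'
#' Re-estimates the low-range (and, where the window supports a 13-30 Hz
#' fit, high-range) spectral exponent of the fractal component on
#' `n_windows` consecutive overlapping windows displaced by `step_s`
#' seconds, and locates the full-segment exponent within each window
#' distribution. The representativeness p is the percentile-based two-sided
#' `p = 2 * min(r, 1 - r)` with `r` the fraction of window estimates at or
#' below the full-segment value.
#'
#' @param signal numeric vector.
#' @param cfg an [irasa_config()].
#' @param window_s window sizes in seconds (default `c(2.5, 5, 10)`).
#' @param n_windows number of windows per size (default 100).
#' @param step_s displacement between consecutive windows in seconds
#'   (default 0.5).
#' @param f_break breakpoint for the bimodal fit (default 13 Hz).
#' @return data.frame with one row per window size and exponent
#'   (`beta_lo`/`beta_hi`): the full-segment estimate, the window
#'   distribution's 2.5 and 97.5 percentiles, whether the full-segment value
#'   lies inside that band, and the representativeness p.
#' @export
sliding_window_validation <- function(signal, cfg = irasa_config(),
                                      window_s = c(2.5, 5, 10),
                                      n_windows = 100L, step_s = 0.5,
                                      f_break = 13) {
  n <- length(signal)
  full <- slope_pair(signal, cfg, f_break)
  out <- list()
  for (w in window_s) {
    wlen <- round(w * cfg$srate)
    step <- round(step_s * cfg$srate)
    last_start <- (n_windows - 1L) * step + 1L
    if (wlen > n) {
      stop_invalid(sprintf("window of %g s (%d samples) exceeds the signal (%d samples)",
                           w, wlen, n))
    }
    if (last_start + wlen - 1L > n) {
      stop_invalid(sprintf(
        "%d windows of %g s with %g s steps need %d samples; signal has %d",
        n_windows, w, step_s, last_start + wlen - 1L, n))
    }
    betas <- vapply(seq_len(n_windows), function(i) {
      s <- (i - 1L) * step + 1L
      unlist(slope_pair(signal[s:(s + wlen - 1L)], cfg, f_break))
    }, numeric(2L))
    for (which_b in rownames(betas)) {
      bw <- betas[which_b, ]
      fb <- full[[which_b]]
      qs <- stats::quantile(bw, c(0.025, 0.975), names = FALSE)
      r <- mean(bw <= fb)
      out[[length(out) + 1L]] <- data.frame(
        window_s = w, exponent = which_b, full_segment = fb,
        q2.5 = qs[1], q97.5 = qs[2],
        inside_band = fb >= qs[1] & fb <= qs[2],
        p_representative = max(min(2 * min(r, 1 - r), 1), 1 / n_windows)
      )
    }
  }
  do.call(rbind, out)
}

# beta_lo / beta_hi of the fractal component of one signal
slope_pair <- function(signal, cfg, f_break) {
  dec <- irasa_separate(signal, cfg)
  fit <- fit_bimodal(dec$freqs, dec$fractal, f_break = f_break,
                     full_range = cfg$frange)
  list(beta_lo = fit$beta_lo, beta_hi = fit$beta_hi)
}

#' Channel-wise (or network-wise) group comparison over a band-power table
#'
#' Runs [compare_groups()] for every (band, component, location) cell of a
#' tidy band-power table and applies BH-FDR within each band x component
#' family of locations (the correction family used for each scalp map).
#' Effect size and post-hoc power accompany every comparison.
#'
#' @param tab data.frame with columns `subject`, `group`, `band`,
#'   `component`, `value` and a location column (`channel` or `network`).
#' @param location name of the location column (default `"channel"`).
#' @param alpha FDR level (default .05).
#' @return data.frame with one row per cell: `test_used`, `p_raw`, `p_adj`,
#'   `significant`, `d`, `power`.
#' @export
group_comparison_table <- function(tab, location = "channel", alpha = 0.05) {
  need <- c("subject", "group", "band", "component", "value", location)
  if (!all(need %in% names(tab))) {
    stop_invalid("table must have columns: ", paste(need, collapse = ", "))
  }
  groups <- sort(unique(tab$group))
  if (length(groups) != 2L) stop_invalid("need exactly two groups")
  cells <- unique(tab[, c("band", "component", location)])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- tab$band == cells$band[i] & tab$component == cells$component[i] &
      tab[[location]] == cells[[location]][i]
    x <- tab$value[sel & tab$group == groups[1]]
    y <- tab$value[sel & tab$group == groups[2]]
    cmp <- compare_groups(x, y, alpha)
    ep <- effect_size_and_power(x, y, alpha)
    cbind(cells[i, , drop = FALSE],
          data.frame(test_used = cmp$test_used, p_raw = cmp$p_raw,
                     d = ep$d, power = ep$power))
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res$p_adj <- NA_real_
  res$significant <- NA
  for (fam in split(seq_len(nrow(res)),
                    list(res$band, res$component), drop = TRUE)) {
    adj <- bh_fdr(res$p_raw[fam], alpha)
    res$p_adj[fam] <- adj$p_adj
    res$significant[fam] <- adj$rejected
  }
  res
}
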