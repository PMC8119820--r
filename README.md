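# fractalEEG

Resting-state EEG power spectra mix two kinds of neural activity: a
broadband **scale-free (fractal)** component whose power spectral density
follows a power law `P(f) ∝ f^(−β)`, and **narrow-band oscillations** (such
as occipital alpha) superimposed on it. Band-limited power computed on the
raw spectrum confounds the two, which matters wherever spectral differences
between groups are interpreted — e.g. delta-band differences between
clinical and control cohorts that may originate in the broadband component
rather than in any oscillation.

`fractalEEG` is an R package for neurophysiologists who want to make that
attribution explicit. It implements:

* **IRASA** (irregular-resampling auto-spectral analysis): for resampling
  factors `h` in `[1.05, 1.5]` (20 values), the geometric mean of the PSDs
  of the `h`- and `1/h`-resampled signal leaves power laws invariant while
  displacing oscillatory peaks; the median over the h-set estimates the
  fractal spectrum, and `oscillatory = mixed − fractal`. PSDs are Welch-type
  estimates over 15 overlapping Hanning-tapered subsegments (90% of the
  signal each).
* **Bimodal spectral exponents**: `β_lo` (1–13 Hz) and `β_hi` (13–30 Hz) by
  least squares on log-evenly resampled log-log spectra, with
  `Δβ = β_hi − β_lo` and an F test comparing the bimodal against a unimodal
  fit.
* **Band-limited power** (delta 1–4, theta 4–8, alpha 8–13, beta 13–30 Hz)
  for the mixed, fractal and oscillatory spectra, and aggregation of the 19
  channels of the 10–20 montage onto five resting-state networks.
* **The inferential pipeline**: Lilliefors-routed two-group tests
  (pooled t / Welch t / Mann–Whitney), Benjamini–Hochberg FDR per scalp-map
  family, one-sample Δβ bimodality tests, ANCOVA of mixed power with the
  fractal power as covariate, Cohen's d and post-hoc power.
* **Preprocessing**: zero-phase order-5 Butterworth band-pass (0.5–45 Hz),
  spherical-spline current source density (surface Laplacian),
  standardization to zero mean / unit variance (so the PSD integrates to 1),
  and augmented Dickey–Fuller stationarity screening.
* **A synthetic cohort generator** (two groups × 14 subjects × 19 channels ×
  2^14 samples at 250 Hz, piecewise power-law spectra with superimposed
  oscillations and configurable group effects) so the entire pipeline is
  testable without external recordings, plus EDF and matrix I/O for real
  data.

## Worked example

```r
library(fractalEEG)

# a 2^14-sample signal with a bimodal 1/f background (beta_lo = 1,
# beta_hi = 1.8, breakpoint 13 Hz) and an alpha oscillation at 10 Hz
x <- generate_scalefree_noise(16384, 250, beta_lo = 1, beta_hi = 1.8,
                              f_break = 13, seed = 1)
y <- add_oscillation(x, fs = 250, center = 10, amplitude = 0.3,
                     bandwidth = 2, seed = 2)

dec <- irasa_separate(y, irasa_config())
dec
#> <spectral_decomposition> 3801 bins over [1.00708, 29.9988] Hz

fit_bimodal(dec$freqs, dec$fractal)
#> <bimodal_fit> beta_lo 0.836, beta_hi 2.394 (delta 1.558); beta_uni 1.058;
#>   GoF F = 34.43, p = 6.07e-12

head(subset(decomposition_blp(dec), band %in% c("delta", "alpha")), 6)
#>     band   component        blp
#> 1  delta       mixed 0.12963117
#> 3  alpha       mixed 0.41501168
#> 5  delta     fractal 0.09163222
#> 7  alpha     fractal 0.04628812
#> 9  delta oscillatory 0.03799895
#> 11 alpha oscillatory 0.36872357
```

Reading the output: the GoF F test strongly prefers the bimodal description
(`p ≈ 6e-12`), and most alpha-band power lands in the oscillatory component
(0.369 of 0.415) while delta-band power is mostly fractal — the attribution
the method exists to make. Single-realization exponent estimates carry
estimator noise, and a strong alpha peak pushes `β_hi` upward under the
narrow h-set (here 2.39 against a generating 1.8); that is the documented
motivation for re-running with the broader validation h-set `[1.05, 2.0]`,
which suppresses oscillatory leakage at the cost of capping the analysis at
45/2 = 22.5 Hz. See the methods vignette
(`vignettes/scalefree-oscillatory-eeg.Rmd`) for the estimator-noise model
and every numerical choice.

A cohort-level run — synthesis (or EDF input), preprocessing, decomposition,
band power, exponent fits, RSN aggregation and group statistics with FDR —
is one call:

```r
res <- run_pipeline(pipeline_config(
  synthetic = list(n_per_group = 14),
  out_dir   = "out",
  seed      = 1))
head(res$channel_stats)   # test_used, p_raw, p_adj, significant, d, power
```

It writes tidy CSVs (`band_power.csv`, `fits.csv`, `channel_stats.csv`,
`rsn_stats.csv`, `delta_beta_stats.csv`, `stationarity.csv`), a run log and
the resolved YAML configuration; identical configuration and seed give
byte-identical outputs.

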