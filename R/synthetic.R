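#' Synthetic cohort specification
#'
#' Describes a synthetic resting-state EEG cohort: standardized signals with a
#' piecewise (bimodal) power-law background spectrum, superimposed narrow-band
#' oscillations, two groups of subjects, and configurable additive group
#' effects on the generating parameters. Defaults follow the study conditions
#' this package targets: 2^14 samples at 250 Hz, 13 Hz spectral breakpoint,
#' 14 subjects per group, 19-channel 10-20 montage.
#'
#' Channel heterogeneity (see [default_channel_profile()]) assigns a steeper
#' low-range exponent to frontal channels and a stronger alpha oscillation to
#' occipito-temporal channels, mirroring the characteristic scalp topology of
#' resting EEG.
#'
#' @param n_samples samples per channel (default 16384 = 2^14).
#' @param fs sampling rate in Hz (default 250).
#' @param beta_lo baseline low-range (1-13 Hz) spectral exponent.
#' @param beta_hi baseline high-range (13-30 Hz) spectral exponent.
#' @param f_break breakpoint frequency in Hz (default 13).
#' @param oscillations data.frame with columns `center` (Hz), `amplitude`
#'   (share of total signal variance, in `[0, 1)`), `bandwidth` (Hz); the
#'   default is a single alpha oscillation at 10 Hz.
#' @param n_per_group subjects per group (default 14).
#' @param channel_labels channel labels (default: the 19 10-20 labels).
#' @param channel_profile data.frame of per-channel parameter offsets, as
#'   returned by [default_channel_profile()].
#' @param group_effects list with elements `beta_lo`, `beta_hi`,
#'   `osc_amplitude` (additive offsets applied to group 2) and `channels`
#'   (labels the offsets apply to; `NULL` = all channels).
#' @param seed integer seed; the same seed reproduces the identical cohort.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_cohort()]
#' @export
synthetic_spec <- function(n_samples = 16384L,
                           fs = 250,
                           beta_lo = 1.0,
                           beta_hi = 1.6,
                           f_break = 13,
                           oscillations = data.frame(center = 10,
                                                     amplitude = 0.25,
                                                     bandwidth = 2),
                           n_per_group = 14L,
                           channel_labels = channels_1020(),
                           channel_profile = default_channel_profile(channel_labels),
                           group_effects = list(beta_lo = 0, beta_hi = 0,
                                                osc_amplitude = 0,
                                                channels = NULL),
                           seed = 1L) {
  check_scalar_number(n_samples, "n_samples", positive = TRUE)
  check_scalar_number(fs, "fs", positive = TRUE)
  if (f_break <= 0 || f_break >= fs / 2) {
    stop_invalid("f_break must lie strictly inside (0, Nyquist)")
  }
  if (!all(c("center", "amplitude", "bandwidth") %in% names(oscillations))) {
    stop_invalid("oscillations must have columns center, amplitude, bandwidth")
  }
  if (any(oscillations$amplitude < 0)) {
    stop_invalid("oscillation amplitudes must be >= 0")
  }
  channel_labels <- as.character(channel_labels)
  unknown <- setdiff(channel_labels, montage_1020()$label)
  if (length(unknown)) {
    stop_invalid("unknown channel label(s): ", paste(unknown, collapse = ", "))
  }
  ge <- utils::modifyList(list(beta_lo = 0, beta_hi = 0, osc_amplitude = 0,
                               channels = NULL), as.list(group_effects))
  if (!is.null(ge$channels)) {
    bad <- setdiff(ge$channels, channel_labels)
    if (length(bad)) {
      stop_invalid("group_effects$channels contains unknown label(s): ",
                   paste(bad, collapse = ", "))
    }
  }
  structure(
    list(n_samples = as.integer(n_samples), fs = fs,
         beta_lo = beta_lo, beta_hi = beta_hi, f_break = f_break,
         oscillations = oscillations, n_per_group = as.integer(n_per_group),
         channel_labels = channel_labels, channel_profile = channel_profile,
         group_effects = ge, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Default per-channel parameter offsets for the synthetic cohort
#'
#' Frontal channels (Fp1, Fp2, F3, F4, F7, F8, Fz) receive a steeper low-range
#' exponent (+0.3); occipito-temporal channels (O1, O2, T5, T6) receive a
#' stronger alpha oscillation (+0.25 variance share) and a steeper high-range
#' exponent (+0.3), reproducing qualitatively the frontal-high beta_lo /
#' occipital-high beta_hi scalp topology of resting EEG.
#'
#' @param labels channel labels for which to build the profile.
#' @return data.frame with columns `label`, `d_beta_lo`, `d_beta_hi`,
#'   `d_osc_amplitude` (additive offsets on the spec baselines).
#' @export
default_channel_profile <- function(labels = channels_1020()) {
  frontal <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz")
  occipital <- c("O1", "O2", "T5", "T6")
  data.frame(
    label = labels,
    d_beta_lo = ifelse(labels %in% frontal, 0.3, 0),
    d_beta_hi = ifelse(labels %in% occipital, 0.3, 0),
    d_osc_amplitude = ifelse(labels %in% occipital, 0.25, 0),
    stringsAsFactors = FALSE
  )
}

#' Generate standardized scale-free (piecewise power-law) noise
#'
#' Spectral synthesis: Fourier amplitudes are set to `f^(-beta/2)` piecewise
#' (with `beta = beta_lo` below `f_break` and `beta = beta_hi` above it,
#' amplitude-matched at the breakpoint so the spectrum is continuous), phases
#' are drawn i.i.d. uniform, and the real inverse transform is standardized to
#' zero mean and unit (population) variance.
#'
#' @param n_samples number of samples.
#' @param fs sampling rate in Hz.
#' @param beta_lo,beta_hi spectral exponents in `[-1, 4]` below/above `f_break`.
#' @param f_break breakpoint in Hz, strictly inside `(0, fs/2)`.
#' @param seed integer seed (same seed, same parameters: identical signal).
#' @return numeric vector of length `n_samples`, standardized.
#' @examples
#' x <- generate_scalefree_noise(2048, 250, 1, 1, seed = 1)
#' c(mean(x), var(x) * (length(x) - 1) / length(x))
#' @export
generate_scalefree_noise <- function(n_samples, fs, beta_lo, beta_hi = beta_lo,
                                     f_break = 13, seed = NULL) {
  check_scalar_number(n_samples, "n_samples", positive = TRUE)
  check_scalar_number(fs, "fs", positive = TRUE)
  n <- as.integer(n_samples)
  if (f_break <= 0 || f_break >= fs / 2) {
    stop_invalid("f_break must lie strictly inside (0, Nyquist)")
  }
  for (b in c(beta_lo, beta_hi)) {
    if (b < -1 || b > 4) stop_invalid("beta exponents must lie in [-1, 4]")
  }
  with_seed(seed, {
    nf <- n %/% 2L                       # positive-frequency bins 1..nf
    f <- fs * seq_len(nf) / n
    amp <- ifelse(f < f_break,
                  f^(-beta_lo / 2),
                  f_break^(-beta_lo / 2) * (f / f_break)^(-beta_hi / 2))
    phase <- stats::runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phase)
    # Hermitian assembly; Nyquist bin (even n) must be real.
    if (n %% 2L == 0L) spec[nf] <- complex(real = amp[nf] * cos(phase[nf]))
    full <- complex(real = numeric(n))
    full[2:(nf + 1L)] <- spec
    full[n:(n - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    standardize_vector(x)
  })
}

#' Superimpose a narrow-band oscillation on a signal
#'
#' The oscillation is realized as narrow-band Gaussian noise: white noise
#' passed through a zero-phase 4th-order Butterworth band-pass of width
#' `bandwidth` around `center`, giving a broad spectral peak like
#' physiological alpha (a pure sinusoid would give an unrealistically sharp
#' line). `bandwidth = 0` instead gives a random-phase sinusoid (a spectral
#' line), for cases where a deterministic peak location is needed.
#' `amplitude` is the share of total output variance carried by the
#' oscillation; the mixture is re-standardized.
#'
#' @param signal numeric input signal.
#' @param fs sampling rate in Hz.
#' @param center peak frequency in Hz, `0 < center < fs/2`.
#' @param amplitude oscillatory share of total variance, in `[0, 1)`;
#'   `amplitude = 0` returns the re-standardized input unchanged.
#' @param bandwidth full bandwidth of the band-pass in Hz; `0` for a pure
#'   sinusoid.
#' @param seed integer seed for the oscillation noise.
#' @return standardized numeric vector, same length as `signal`.
#' @export
add_oscillation <- function(signal, fs, center, amplitude, bandwidth = 2,
                            seed = NULL) {
  check_scalar_number(fs, "fs", positive = TRUE)
  if (center <= 0 || center >= fs / 2) {
    stop_invalid("oscillation center must lie strictly inside (0, Nyquist)")
  }
  if (amplitude < 0 || amplitude >= 1) {
    stop_invalid("amplitude must be in [0, 1) (share of total variance)")
  }
  x <- standardize_vector(signal)
  if (amplitude == 0) return(x)
  osc <- if (bandwidth == 0) {
    ph <- with_seed(seed, stats::runif(1, 0, 2 * pi))
    t <- seq_along(x) / fs
    sqrt(2) * sin(2 * pi * center * t + ph)
  } else {
    lo <- max(center - bandwidth / 2, 1e-3)
    hi <- min(center + bandwidth / 2, fs / 2 * 0.999)
    with_seed(seed, {
      w <- stats::rnorm(length(x))
      standardize_vector(zero_phase_filter(w, fs, lo, hi, order = 4L))
    })
  }
  standardize_vector(sqrt(1 - amplitude) * x + sqrt(amplitude) * osc)
}

#' Generate a two-group synthetic cohort of recordings
#'
#' Each subject is a 19-channel (by default) recording whose channels are
#' independent piecewise power-law noises with superimposed oscillations;
#' per-channel parameters are the spec baselines plus the channel profile
#' offsets, and group 2 additionally receives the spec's `group_effects`
#' offsets on the selected channels. Every subject and channel uses a distinct
#' seed derived from `spec$seed`, so the cohort is fully reproducible from the
#' spec alone.
#'
#' @param spec a [synthetic_spec()].
#' @return list of [recording()] objects (group 1 first), each carrying its
#'   generating parameters in `attr(rec, "ground_truth")`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labels <- spec$channel_labels
  prof <- spec$channel_profile[match(labels, spec$channel_profile$label), ]
  ge <- spec$group_effects
  ge_channels <- if (is.null(ge$channels)) labels else ge$channels
  recs <- vector("list", 2L * spec$n_per_group)
  k <- 0L
  for (g in 1:2) {
    for (s in seq_len(spec$n_per_group)) {
      dat <- matrix(0, nrow = length(labels), ncol = spec$n_samples)
      truth <- data.frame(label = labels, beta_lo = NA_real_,
                          beta_hi = NA_real_, osc_amplitude = NA_real_)
      for (ci in seq_along(labels)) {
        in_ge <- g == 2L && labels[ci] %in% ge_channels
        b_lo <- spec$beta_lo + prof$d_beta_lo[ci] + if (in_ge) ge$beta_lo else 0
        b_hi <- spec$beta_hi + prof$d_beta_hi[ci] + if (in_ge) ge$beta_hi else 0
        # Seeds stay far below 2^31 for any plausible cohort size.
        sd_ch <- spec$seed + 10000L * k + 100L * ci
        x <- generate_scalefree_noise(spec$n_samples, spec$fs, b_lo, b_hi,
                                      spec$f_break, seed = sd_ch)
        amp_tot <- 0
        for (oi in seq_len(nrow(spec$oscillations))) {
          o <- spec$oscillations[oi, ]
          a <- o$amplitude + prof$d_osc_amplitude[ci] +
            if (in_ge) ge$osc_amplitude else 0
          a <- min(max(a, 0), 0.95)
          amp_tot <- amp_tot + a
          x <- add_oscillation(x, spec$fs, o$center, a, o$bandwidth,
                               seed = sd_ch + oi)
        }
        dat[ci, ] <- x
        truth$beta_lo[ci] <- b_lo
        truth$beta_hi[ci] <- b_hi
        truth$osc_amplitude[ci] <- amp_tot
      }
      rec <- recording(dat, spec$fs, labels, group = paste0("G", g))
      attr(rec, "ground_truth") <- truth
      attr(rec, "subject") <- sprintf("G%d_S%02d", g, s)
      k <- k + 1L
      recs[[k]] <- rec
    }
  }
  recs
}
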