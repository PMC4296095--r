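#' Gait characteristics from a 10-second trunk-acceleration epoch
#'
#' These functions compute the individual gait characteristics that together
#' make up the 30-characteristic feature vector: spectral and autocorrelation
#' measures of rhythm, symmetry and smoothness, nonlinear measures of
#' regularity (sample entropy) and stability (local dynamic stability), and
#' an inverted-pendulum estimate of gait speed. [extract_features()] applies
#' all of them to one epoch.
#'
#' @name gait-characteristics
NULL

#' Stride frequency of an epoch
#'
#' Locates the dominant periodicity of the vertical axis by an exhaustive
#' peak search of the unbiased normalized autocorrelation over the stride-lag
#' band (by default stride frequencies 0.4-1.6 Hz), with parabolic lag
#' refinement. A perfectly step-symmetric signal is stride-ambiguous (one
#' stride looks like two identical steps); ties resolve to the smallest peak
#' lag.
#'
#' @param vt Vertical (VT) acceleration signal, m/s^2.
#' @param fs Sampling rate, Hz.
#' @param band Stride-frequency search band in Hz.
#' @param min_autocorr Detection floor: if no autocorrelation peak in the band
#'   reaches this value the epoch has no defined stride frequency and `NA` is
#'   returned (the epoch is dropped downstream).
#' @return Stride frequency in Hz, or `NA_real_` when undefined.
#' @examples
#' ep <- synth_gait_epoch(gait_signal_params(stride_frequency = 1), seed = 1)
#' stride_frequency(ep$acc_vt, 100)
#' @export
stride_frequency <- function(vt, fs, band = c(0.4, 1.6), min_autocorr = 0.25) {
  n <- length(vt)
  if (sd(vt) == 0) return(NA_real_)
  lag_min <- max(2L, floor(fs / band[2]))
  lag_max <- min(n - 2L, ceiling(fs / band[1]))
  if (lag_max <= lag_min) return(NA_real_)
  lags <- lag_min:lag_max
  r <- autocorr_unbiased(vt, lags)
  i <- which.max(r)
  if (!is.finite(r[i]) || r[i] < min_autocorr) return(NA_real_)
  pk <- parabolic_peak(r, i)
  fs / (lags[i] + pk$offset)
}

#' Root-mean-square acceleration
#'
#' RMS of the mean-centered signal (dynamic acceleration only).
#'
#' @param x Numeric signal.
#' @return RMS in the signal's units.
#' @export
rms <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Stride regularity
#'
#' Value of the unbiased normalized autocorrelation at the lag nearest one
#' stride, peak-refined within +-10% of the nominal stride lag. 1 means
#' perfect stride-to-stride self-similarity.
#'
#' @param x Acceleration signal for one axis.
#' @param fs Sampling rate, Hz.
#' @param f_stride Stride frequency in Hz (from [stride_frequency()]).
#' @return Autocorrelation value, typically in `[-1, 1]`.
#' @export
stride_regularity <- function(x, fs, f_stride) {
  if (!is.finite(f_stride)) return(NA_real_)
  lag0 <- fs / f_stride
  lags <- max(1L, floor(lag0 * 0.9)):min(length(x) - 2L, ceiling(lag0 * 1.1))
  if (lags[1] >= length(x) / 2) return(NA_real_)
  r <- autocorr_unbiased(x, lags)
  if (all(!is.finite(r))) return(NA_real_)
  # grid maximum, not parabolic: the unbiased autocorrelation of a periodic
  # signal peaks with a kink, which a parabola overshoots past 1
  max(r)
}

#' Low-frequency percentage
#'
#' Percentage of Welch spectral power below a cutoff, relative to the total
#' power between 0.1 Hz and the Nyquist frequency. Cutoffs follow the axis
#' convention 0.7 Hz (VT/AP) and 10 Hz (ML).
#'
#' @inheritParams stride_regularity
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param window_s,overlap Welch segment length (s) and fractional overlap.
#'   The default segment length equals the 10-s epoch, where the Welch
#'   estimate reduces to a single Hann periodogram; shorter windows blur
#'   spectral lines near the 0.7 Hz cutoff.
#' @param band_min Lower edge of the total-power band, Hz.
#' @return Percentage in `[0, 100]`, or `NA` for a zero-power signal.
#' @export
low_frequency_percentage <- function(x, fs, cutoff, window_s = 10,
                                     overlap = 0.5, band_min = 0.1) {
  stopifnot(cutoff < fs / 2)
  spec <- welch_psd(x, fs, window_s, overlap)
  tot <- sum(spec$psd[spec$freq >= band_min])
  if (tot == 0) return(NA_real_)
  low <- sum(spec$psd[spec$freq >= band_min & spec$freq < cutoff])
  100 * low / tot
}

#' Index of harmonicity
#'
#' Fraction of spectral power carried by the fundamental gait frequency
#' relative to the fundamental plus its first `n_harmonics` higher harmonics
#' (powers integrated over +-1 spectral bin around each harmonic). 1 means a
#' purely sinusoidal, fully harmonic signal.
#'
#' @inheritParams stride_regularity
#' @param fundamental Fundamental frequency in Hz (step frequency for VT/AP,
#'   stride frequency for ML).
#' @param n_harmonics Number of higher harmonics in the denominator.
#' @return Value in `[0, 1]`, or `NA` when the harmonic power is zero.
#' @export
index_of_harmonicity <- function(x, fs, fundamental, n_harmonics = 5L) {
  if (!is.finite(fundamental) || fundamental <= 0) return(NA_real_)
  n <- length(x)
  w <- hann_window(n)
  X <- Mod(fft((x - mean(x)) * w))^2
  nf <- floor(n / 2) + 1L
  pw <- X[seq_len(nf)]
  df <- fs / n
  harm_power <- function(f0) {
    i <- round(f0 / df) + 1L
    sel <- max(1L, i - 1L):min(nf, i + 1L)
    sum(pw[sel])
  }
  p <- vapply(fundamental * seq_len(n_harmonics + 1L), harm_power, numeric(1))
  denom <- sum(p)
  if (denom == 0) return(NA_real_)
  min(1, max(0, p[1] / denom))
}

#' Harmonic ratio
#'
#' Ratio of summed spectral amplitudes at even stride harmonics to odd stride
#' harmonics (first `n_harmonics` harmonics, amplitudes read within +-1 bin
#' of each harmonic). For VT and AP the in-phase content sits at even stride
#' harmonics so the ratio is even/odd; the ML axis is symmetric at stride
#' frequency and the ratio is inverted (odd/even). Higher values mean more
#' symmetric gait.
#'
#' @inheritParams stride_regularity
#' @param axis One of `"vt"`, `"ml"`, `"ap"`.
#' @param n_harmonics Number of stride harmonics summed.
#' @param cap Value returned (with a `"capped"` attribute) when the
#'   denominator amplitude is essentially zero.
#' @return Non-negative ratio; `attr(., "capped")` is `TRUE` when capped.
#' @export
harmonic_ratio <- function(x, fs, f_stride, axis = c("vt", "ml", "ap"),
                           n_harmonics = 20L, cap = 100) {
  axis <- match.arg(axis)
  if (!is.finite(f_stride) || f_stride <= 0) return(NA_real_)
  spec <- amp_spectrum(x, fs)
  ks <- seq_len(min(n_harmonics, floor((fs / 2) / f_stride)))
  if (length(ks) < 2) return(NA_real_)
  amps <- vapply(ks * f_stride, function(f0) peak_amp_near(spec, f0), numeric(1))
  even <- sum(amps[ks %% 2 == 0])
  odd <- sum(amps[ks %% 2 == 1])
  num <- if (axis == "ml") odd else even
  den <- if (axis == "ml") even else odd
  ratio <- if (den == 0) Inf else num / den
  if (ratio >= cap) return(structure(cap, capped = TRUE))
  ratio
}

#' Frequency variability
#'
#' Coefficient of variation of the instantaneous dominant frequency,
#' estimated in 50%-overlapping 2.5-s sub-windows within the gait band.
#' Captures stride-to-stride wander of the gait rhythm; scale-invariant.
#'
#' @inheritParams stride_regularity
#' @param band Frequency band searched for the dominant peak, Hz.
#' @param window_s,overlap Sub-window length (s) and fractional overlap.
#' @return Dimensionless CV, or `NA` with fewer than 3 valid sub-windows.
#' @export
frequency_variability <- function(x, fs, band = c(0.5, 3.5),
                                  window_s = 2.5, overlap = 0.5) {
  n <- length(x)
  seg <- round(window_s * fs)
  if (seg >= n) return(NA_real_)
  step <- max(1L, floor(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  fhat <- vapply(starts, function(s) {
    dominant_frequency(x[s:(s + seg - 1L)], fs, band)
  }, numeric(1))
  fhat <- fhat[is.finite(fhat)]
  if (length(fhat) < 3 || mean(fhat) == 0) return(NA_real_)
  sd(fhat) / mean(fhat)
}

#' Local dynamic stability (short-term logarithmic divergence rate)
#'
#' Rosenstein-style estimate: the signal is delay-embedded, each embedded
#' point is paired with its nearest neighbor outside a one-stride temporal
#' exclusion window, and the slope of the mean log-divergence curve over
#' 0-0.5 stride is returned, in 1/s. Higher divergence means less stable
#' gait.
#'
#' @inheritParams stride_regularity
#' @param dim Embedding dimension.
#' @param delay Embedding delay in samples.
#' @param fit_fraction_stride Length of the fit range as a fraction of one
#'   stride time.
#' @return Divergence rate in 1/s, or `NA` when too few valid neighbor pairs
#'   exist.
#' @export
local_dynamic_stability <- function(x, fs, f_stride, dim = 5L, delay = 10L,
                                    fit_fraction_stride = 0.5) {
  if (!is.finite(f_stride) || f_stride <= 0) return(NA_real_)
  n <- length(x)
  m <- n - (dim - 1L) * delay
  if (m < 100L) return(NA_real_)
  stride_samples <- round(fs / f_stride)
  K <- max(2L, round(fit_fraction_stride * stride_samples))
  m0 <- m - K
  if (m0 < 50L) return(NA_real_)
  X <- vapply(seq_len(dim), function(d) {
    x[((d - 1L) * delay + 1L):((d - 1L) * delay + m)]
  }, numeric(m))
  X0 <- X[seq_len(m0), , drop = FALSE]
  # squared-distance matrix with temporal exclusion of one stride
  sq <- rowSums(X0^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X0)
  idx <- seq_len(m0)
  excl <- abs(outer(idx, idx, "-")) <= stride_samples
  D2[excl] <- Inf
  nn <- max.col(-D2, ties.method = "first")
  if (!length(nn)) return(NA_real_)
  logd <- matrix(NA_real_, nrow = m0, ncol = K + 1L)
  for (k in 0:K) {
    d <- sqrt(rowSums((X[idx + k, , drop = FALSE] - X[nn + k, , drop = FALSE])^2))
    logd[, k + 1L] <- log(pmax(d, 1e-12))
  }
  y <- colMeans(logd)
  ks <- 0:K
  slope <- coef(lm(y ~ ks))[2]
  unname(slope * fs)
}

#' Sample entropy
#'
#' Negative log conditional probability that template sequences matching for
#' `m` points (within Chebyshev tolerance `r` times the signal SD) also match
#' for `m + 1` points; self-matches excluded. Lower values mean a more
#' regular signal. The template-pair counting runs in compiled code; the test
#' suite verifies it against a direct O(N^2) counter.
#'
#' @param x Numeric signal.
#' @param m Template length in samples.
#' @param r Tolerance radius as a fraction of `sd(x)` (or absolute when
#'   `r_is_fraction = FALSE`).
#' @param r_is_fraction Interpret `r` relative to the signal SD?
#' @return Non-negative entropy, or `NA` when no template pairs match (the
#'   feature is undefined rather than infinite).
#' @examples
#' sample_entropy(sin(seq(0, 20 * pi, length.out = 500)))
#' @export
sample_entropy <- function(x, m = 5L, r = 0.3, r_is_fraction = TRUE) {
  stopifnot(m >= 1, r > 0)
  n <- length(x)
  if (n <= m + 1L) return(NA_real_)
  r_abs <- if (r_is_fraction) r * sd(x) else r
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), r_abs)
  if (cnt$B == 0 || cnt$A == 0) return(NA_real_)
  -log(cnt$A / cnt$B)
}

#' Amplitude of the dominant spectral peak
#'
#' Amplitude (not power) of the spectral peak nearest the axis-appropriate
#' fundamental, window-gain corrected, from a heavily zero-padded Hann
#' spectrum.
#'
#' @inheritParams stride_regularity
#' @param fundamental Expected fundamental frequency in Hz; the peak is
#'   searched within +-30% of it.
#' @return Peak amplitude in m/s^2, or `NA` when undefined.
#' @export
dominant_frequency_amplitude <- function(x, fs, fundamental) {
  if (!is.finite(fundamental) || fundamental <= 0) return(NA_real_)
  spec <- amp_spectrum(x, fs, pad = 8L)
  sel <- which(spec$freq >= fundamental * 0.7 & spec$freq <= fundamental * 1.3)
  if (!length(sel)) return(NA_real_)
  max(spec$amp[sel])
}

#' Inverted-pendulum gait speed and speed variability
#'
#' High-pass filters and double-integrates the vertical acceleration to
#' vertical displacement, reads the per-step vertical excursion `h`, converts
#' it to step length `2 * sqrt(2 * l * h - h^2)` with leg length `l`, and
#' multiplies by step frequency. Speed variability is the SD of per-step
#' speeds.
#'
#' @inheritParams stride_regularity
#' @param vt Vertical acceleration, m/s^2.
#' @param leg_length Leg length `l` in meters.
#' @param highpass_hz High-pass cutoff (Butterworth order 2, zero-phase)
#'   applied to acceleration and after each integration to curb drift.
#' @param trim_s Seconds trimmed from each end before step segmentation, to
#'   discard filter transients.
#' @return A list with elements `speed` and `variability`, m/s.
#' @export
gait_speed_and_variability <- function(vt, fs, f_stride, leg_length = 0.9,
                                       highpass_hz = 0.5, trim_s = 1) {
  if (!is.finite(f_stride) || f_stride <= 0) {
    return(list(speed = NA_real_, variability = NA_real_))
  }
  if (sd(vt) == 0) {
    return(list(speed = 0, variability = 0))
  }
  f_step <- 2 * f_stride
  hp <- signal::butter(2, highpass_hz / (fs / 2), type = "high")
  a <- signal::filtfilt(hp, vt - mean(vt))
  v <- signal::filtfilt(hp, cumsum(a) / fs)
  z <- signal::filtfilt(hp, cumsum(v) / fs)
  trim <- round(trim_s * fs)
  z <- z[(trim + 1L):(length(z) - trim)]
  step_len <- round(fs / f_step)
  n_steps <- floor(length(z) / step_len)
  if (n_steps < 2) return(list(speed = NA_real_, variability = NA_real_))
  h <- vapply(seq_len(n_steps), function(i) {
    seg <- z[((i - 1L) * step_len + 1L):(i * step_len)]
    max(seg) - min(seg)
  }, numeric(1))
  h <- pmin(h, 2 * leg_length) # geometric bound of the pendulum model
  step_length <- 2 * sqrt(pmax(0, 2 * leg_length * h - h^2))
  speeds <- step_length * f_step
  list(speed = mean(speeds), variability = sd(speeds))
}
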