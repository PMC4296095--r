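# Internal spectral helpers shared by the gait characteristics.

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann windows and 50% overlap, the
#' spectral estimate used for the low-frequency-percentage characteristic.
#' One-sided, density scaling (power = sum(psd) * df).
#'
#' @param x Numeric signal (mean is removed per segment).
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (capped at the signal length).
#' @param overlap Fractional overlap between segments.
#' @return A tibble with columns `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 5, overlap = 0.5) {
  n <- length(x)
  seg <- min(n, round(window_s * fs))
  step <- max(1L, floor(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- hann_window(seg)
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(seg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    xi <- x[s:(s + seg - 1L)]
    xi <- (xi - mean(xi)) * w
    X <- fft(xi)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) * scale
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when seg is even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (seg %% 2 == 0) dbl[nf] <- 1
  tibble::tibble(freq = (seq_len(nf) - 1L) * fs / seg, psd = psd * dbl)
}

# Amplitude spectrum of the full (Hann-windowed, zero-padded) epoch.
# Coherent-gain corrected so a pure sinusoid of amplitude A peaks at A.
amp_spectrum <- function(x, fs, pad = 4L) {
  n <- length(x)
  w <- hann_window(n)
  xw <- (x - mean(x)) * w
  nfft <- n * pad
  X <- fft(c(xw, numeric(nfft - n)))
  nf <- floor(nfft / 2) + 1L
  list(
    freq = (seq_len(nf) - 1L) * fs / nfft,
    amp = 2 * Mod(X[seq_len(nf)]) / sum(w),
    df_bin = fs / n # pre-padding bin width, the +-1 bin neighbourhood unit
  )
}

# Largest amplitude within +-1 (original) bin of a target frequency.
peak_amp_near <- function(spec, f0) {
  sel <- which(abs(spec$freq - f0) <= spec$df_bin)
  if (!length(sel)) return(0)
  max(spec$amp[sel])
}

# Parabolic interpolation of a discrete peak location.
parabolic_peak <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(list(offset = 0, value = y[i]))
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(list(offset = 0, value = y[i]))
  d <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  list(offset = d, value = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * d)
}

# Dominant frequency of a (sub)window within a band, via padded Hann FFT
# with parabolic refinement. Returns NA when the band holds no power.
dominant_frequency <- function(x, fs, band, nfft_min = 4096L) {
  n <- length(x)
  w <- hann_window(n)
  xw <- (x - mean(x)) * w
  nfft <- max(nfft_min, n)
  X <- Mod(fft(c(xw, numeric(nfft - n))))[seq_len(floor(nfft / 2) + 1L)]
  freq <- (seq_along(X) - 1L) * fs / nfft
  sel <- which(freq >= band[1] & freq <= band[2])
  if (!length(sel) || all(X[sel] == 0)) return(NA_real_)
  i <- sel[which.max(X[sel])]
  pk <- parabolic_peak(X, i)
  (i - 1 + pk$offset) * fs / nfft
}

# Unbiased normalized autocorrelation at a set of integer lags.
# r(k) = [sum(x_t x_{t+k})/(N-k)] / [sum(x_t^2)/N], x mean-centered.
autocorr_unbiased <- function(x, lags) {
  x <- x - mean(x)
  n <- length(x)
  c0 <- sum(x^2) / n
  if (c0 == 0) return(rep(NA_real_, length(lags)))
  vapply(lags, function(k) {
    sum(x[seq_len(n - k)] * x[(k + 1):n]) / (n - k) / c0
  }, numeric(1))
}
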