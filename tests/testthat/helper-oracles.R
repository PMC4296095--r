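# Independent oracles, kept deliberately naive: direct definitional
# computations against which the package implementations are verified.

# O(N^2) sample-entropy template counter (Chebyshev distance, absolute
# tolerance, self-matches excluded).
sampen_brute <- function(x, m, r_abs) {
  n <- length(x)
  A <- 0
  B <- 0
  for (i in 1:(n - m)) {
    for (j in i:(n - m)) {
      if (j == i) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r_abs) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r_abs) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# All-pairs concordance count AUC (ties count 1/2).
auc_brute <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (a in pos) {
    for (b in neg) {
      s <- s + (a > b) + 0.5 * (a == b)
    }
  }
  s / (length(pos) * length(neg))
}

# Grid-search maximizer of the Bernoulli log-likelihood for a univariate
# logistic model (intercept + slope), refined to ~1e-5 resolution.
logit_grid_oracle <- function(x, y, span = 8, iters = 6) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    p <- plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  c0 <- 0
  c1 <- 0
  width <- span
  for (it in seq_len(iters)) {
    g0 <- seq(c0 - width, c0 + width, length.out = 41)
    g1 <- seq(c1 - width, c1 + width, length.out = 41)
    vals <- outer(g0, g1, Vectorize(ll))
    best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    c0 <- g0[best[1]]
    c1 <- g1[best[2]]
    width <- width / 10
  }
  c(intercept = c0, slope = c1)
}

# Unbiased normalized autocorrelation at one lag, written as explicit sums.
autocorr_oracle <- function(x, k) {
  x <- x - mean(x)
  n <- length(x)
  num <- 0
  for (t in 1:(n - k)) num <- num + x[t] * x[t + k]
  (num / (n - k)) / (sum(x^2) / n)
}

# Spectral power fractions from the plain rectangular periodogram.
lowfreq_oracle <- function(x, fs, cutoff, band_min = 0.1) {
  n <- length(x)
  X <- Mod(fft(x - mean(x)))^2
  nf <- floor(n / 2) + 1
  freq <- (seq_len(nf) - 1) * fs / n
  pw <- X[seq_len(nf)]
  100 * sum(pw[freq >= band_min & freq < cutoff]) / sum(pw[freq >= band_min])
}

# ICC(A,1) via R's own two-way ANOVA decomposition.
icc_aov_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

make_sine_epoch <- function(freqs, amps, fs = 100, n = 1000, axis_fill = 0.5) {
  t <- (0:(n - 1)) / fs
  x <- rowSums(vapply(seq_along(freqs), function(i) {
    amps[i] * sin(2 * pi * freqs[i] * t)
  }, numeric(n)))
  x
}

# quiet epoch-level helper: symmetric, noiseless, unit even harmonic on VT
pure_params <- function(f = 1, vt_amp = 1) {
  gait_signal_params(
    stride_frequency = f,
    harmonic_amplitudes_even = list(vt = vt_amp, ml = 0.4, ap = 1),
    harmonic_amplitudes_odd = list(vt = 0.5, ml = 0.8, ap = 0.4),
    asymmetry = 0, freq_jitter_sd = 0, noise_sd = 0
  )
}
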