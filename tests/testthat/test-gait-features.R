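fs <- 100
t10 <- (0:999) / fs

test_that("rms matches closed forms and the definitional sum", {
  expect_equal(rms(sin(2 * pi * 2 * t10)), 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(rms(rep(0, 100)), 0)
  x <- c(0.3, -1.2, 2.5, 0.1, -0.7, 1.9, -2.2, 0.8, -0.4, 1.1)
  expect_equal(rms(x), sqrt(sum((x - mean(x))^2) / length(x)), tolerance = 1e-12)
})

test_that("stride frequency is found for clean and jittered gait, not noise", {
  ep <- synth_gait_epoch(pure_params(f = 1), seed = 1)
  expect_equal(stride_frequency(ep$acc_vt, fs), 1, tolerance = 0.02)

  withr::with_seed(5, {
    wn <- rnorm(1000)
  })
  expect_true(is.na(stride_frequency(wn, fs)))

  pj <- gait_signal_params(
    stride_frequency = 0.9,
    asymmetry = 0.3, freq_jitter_sd = 0.02, noise_sd = 0.1
  )
  epj <- synth_gait_epoch(pj, seed = 3)
  f_hat <- stride_frequency(epj$acc_vt, fs)
  expect_equal(f_hat, 0.9, tolerance = 0.05 / 0.9)

  # exhaustive integer-lag oracle agrees to within one lag of resolution
  lags <- 63:250
  r <- vapply(lags, function(k) autocorr_oracle(epj$acc_vt, k), numeric(1))
  f_oracle <- fs / lags[which.max(r)]
  expect_equal(f_hat, f_oracle, tolerance = 0.02)
})

test_that("stride regularity: periodic = 1, white noise small, oracle equality", {
  ep <- synth_gait_epoch(pure_params(f = 1), seed = 1)
  expect_equal(stride_regularity(ep$acc_vt, fs, 1), 1, tolerance = 1e-6)

  withr::with_seed(6, {
    wn <- rnorm(1000)
  })
  expect_lt(abs(stride_regularity(wn, fs, 1)), 0.15)

  # periodic + noise at SNR 4:1: equals the definitional autocovariance ratio
  withr::with_seed(7, {
    sig <- sin(2 * pi * 1 * t10) + rnorm(1000, 0, 0.25)
  })
  got <- stride_regularity(sig, fs, 1)
  lags <- 90:110
  oracle <- max(vapply(lags, function(k) autocorr_oracle(sig, k), numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("low-frequency percentage matches closed forms and the periodogram", {
  hi <- sin(2 * pi * 2 * t10)
  lo <- sin(2 * pi * 0.5 * t10)
  expect_lt(low_frequency_percentage(hi, fs, 0.7), 1)
  expect_gt(low_frequency_percentage(lo, fs, 0.7), 99)
  mix <- hi + lo
  got <- low_frequency_percentage(mix, fs, 0.7)
  expect_equal(got, 50, tolerance = 2, ignore_attr = TRUE)
  expect_equal(got, lowfreq_oracle(mix, fs, 0.7), tolerance = 2)
})

test_that("index of harmonicity matches amplitude-ratio closed forms", {
  f0 <- 2
  pure <- sin(2 * pi * f0 * t10)
  expect_equal(index_of_harmonicity(pure, fs, f0), 1, tolerance = 1e-3)

  two <- sin(2 * pi * f0 * t10) + sin(2 * pi * 2 * f0 * t10)
  expect_equal(index_of_harmonicity(two, fs, f0), 0.5, tolerance = 0.01)

  three <- sin(2 * pi * f0 * t10) + 0.5 * sin(2 * pi * 2 * f0 * t10) +
    0.25 * sin(2 * pi * 3 * f0 * t10)
  expect_equal(index_of_harmonicity(three, fs, f0), 1 / (1 + 0.25 + 0.0625),
               tolerance = 0.01)
})

test_that("harmonic ratio reproduces amplitude ratios and caps cleanly", {
  sig <- 1 * sin(2 * pi * 2 * t10) + 0.5 * sin(2 * pi * 1 * t10)
  expect_equal(harmonic_ratio(sig, fs, 1, "vt"), 2, tolerance = 0.02,
               ignore_attr = TRUE)
  # ML convention is inverted: odd over even
  expect_equal(harmonic_ratio(sig, fs, 1, "ml"), 0.5, tolerance = 0.01,
               ignore_attr = TRUE)

  even_only <- sin(2 * pi * 2 * t10)
  hr <- harmonic_ratio(even_only, fs, 1, "vt")
  expect_equal(as.numeric(hr), 100)
  expect_true(isTRUE(attr(hr, "capped")))
})

test_that("frequency variability: near zero when clean, ordered by jitter, scale-free", {
  quiet <- synth_gait_epoch(pure_params(f = 1), seed = 1)$acc_vt
  expect_lt(frequency_variability(quiet, fs), 0.01)

  mk <- function(j) {
    synth_gait_epoch(gait_signal_params(
      stride_frequency = 1, asymmetry = 0.2,
      freq_jitter_sd = j, noise_sd = 0
    ), seed = 11)$acc_vt
  }
  expect_gt(frequency_variability(mk(0.05), fs), frequency_variability(mk(0.01), fs))
  x <- mk(0.03)
  expect_equal(frequency_variability(3.7 * x, fs), frequency_variability(x, fs),
               tolerance = 1e-12)
})

test_that("local dynamic stability separates closed orbits from noisy ones", {
  sine <- sin(2 * pi * 1 * t10)
  withr::with_seed(9, {
    noisy <- sine + rnorm(1000, 0, 0.3)
    wn <- rnorm(1000)
  })
  lds_sine <- local_dynamic_stability(sine, fs, 1)
  lds_noisy <- local_dynamic_stability(noisy, fs, 1)
  lds_wn <- local_dynamic_stability(wn, fs, 1)
  expect_lt(abs(lds_sine), 0.05 * abs(lds_wn))
  expect_gt(lds_noisy, lds_sine)
  expect_identical(lds_noisy, local_dynamic_stability(noisy, fs, 1))
})

test_that("sample entropy: constant zero, exact oracle match, noise above sine", {
  expect_equal(sample_entropy(rep(2.5, 50)), 0)

  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  got <- sample_entropy(x, m = 2, r = 0.2)
  expect_identical(got, sampen_brute(x, m = 2, r_abs = 0.2 * sd(x)))

  withr::with_seed(10, {
    wn <- rnorm(1000)
  })
  sine <- sin(2 * pi * 1 * t10) * sd(wn) / sd(sin(2 * pi * 1 * t10))
  expect_gt(sample_entropy(wn), sample_entropy(sine))
})

test_that("dominant frequency amplitude is accurate and linear", {
  x <- 2 * sin(2 * pi * 2 * t10)
  expect_equal(dominant_frequency_amplitude(x, fs, 2), 2, tolerance = 0.02)
  expect_equal(dominant_frequency_amplitude(x / 2, fs, 2),
               dominant_frequency_amplitude(x, fs, 2) / 2, tolerance = 1e-9)

  multi <- 1.5 * sin(2 * pi * 2 * t10) + 0.6 * sin(2 * pi * 4 * t10)
  # rectangular periodogram oracle: amplitude of the max bin near 2 Hz
  X <- Mod(fft(multi - mean(multi)))
  amp_bin <- 2 * max(X[round(2 / (fs / 1000)) + (0:2)]) / 1000
  expect_equal(dominant_frequency_amplitude(multi, fs, 2), amp_bin,
               tolerance = 0.02)
})

test_that("inverted-pendulum speed matches the step-length closed form", {
  h <- 0.02
  l <- 0.9
  f_stride <- 1
  a1 <- (2 * pi * 2 * f_stride)^2 * h / 2
  p <- gait_signal_params(
    stride_frequency = f_stride,
    harmonic_amplitudes_even = list(vt = a1, ml = 0.3, ap = 0.8),
    harmonic_amplitudes_odd = list(vt = 0.3, ml = 0.6, ap = 0.3),
    asymmetry = 0, freq_jitter_sd = 0, noise_sd = 0
  )
  ep <- synth_gait_epoch(p, seed = 1)
  sv <- gait_speed_and_variability(ep$acc_vt, fs, f_stride, leg_length = l)
  expected <- 2 * sqrt(2 * l * h - h^2) * 2 * f_stride
  expect_equal(sv$speed, expected, tolerance = 0.05)
  # constant per-step excursions: negligible speed variability
  expect_lt(sv$variability, 0.02 * sv$speed)

  flat <- ep
  flat$acc_vt <- rep(0, nrow(flat))
  sv0 <- gait_speed_and_variability(flat$acc_vt, fs, f_stride)
  expect_equal(sv0$speed, 0)
})

test_that("extract_features fills all 30 characteristics on clean gait", {
  # single-harmonic symmetric signal: fully harmonic and fully regular
  ep <- synth_gait_epoch(pure_params(f = 1), seed = 1)
  feats <- extract_features(ep)
  vals <- unlist(feats[1, gait_feature_names()])
  expect_true(all(is.finite(vals)))
  expect_gt(feats$stride_regularity_vt, 0.99)
  expect_gt(feats$index_of_harmonicity_vt, 0.99)
  expect_equal(feats$stride_time, 1 / feats$stride_frequency, tolerance = 1e-12)
  # perfect symmetry has zero out-of-phase content: harmonic ratios cap,
  # which is flagged, and no other flag is raised
  expect_true(all(grepl("^hr_capped", strsplit(feats$qc_flags, ";")[[1]])))
})

test_that("an all-zero epoch yields rms 0 and everything else undefined", {
  df <- tibble::tibble(
    time_s = t10, acc_vt = 0, acc_ml = 0, acc_ap = 0
  )
  feats <- extract_features(as_accel_epoch(df))
  expect_equal(feats$rms_vt, 0)
  expect_equal(feats$rms_ml, 0)
  other <- setdiff(gait_feature_names(), c("rms_vt", "rms_ml", "rms_ap"))
  expect_true(all(is.na(unlist(feats[1, other]))))
  expect_match(feats$qc_flags, "stride_undefined")
})

test_that("feature extraction is a pure function of epoch and config", {
  ep <- synth_gait_epoch(gait_signal_params(), seed = 13)
  expect_identical(extract_features(ep), extract_features(ep))
})
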