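test_that("a single even harmonic with no stochastic terms is a pure sinusoid", {
  ep <- synth_gait_epoch(pure_params(f = 1, vt_amp = 1), seed = 1)
  expected <- sin(2 * pi * 2 * ep$time_s)
  expect_equal(ep$acc_vt, expected, tolerance = 1e-12)
})

test_that("noise-free epochs are seed-independent and exactly periodic", {
  p <- pure_params(f = 1.25)
  e1 <- synth_gait_epoch(p, seed = 1)
  e2 <- synth_gait_epoch(p, seed = 99)
  expect_identical(e1, e2)

  for (f in c(0.8, 1, 1.25)) {
    ep <- synth_gait_epoch(pure_params(f = f), seed = 1)
    lag <- round(100 / f)
    for (ax in c("acc_vt", "acc_ap")) {
      r <- autocorr_oracle(ep[[ax]], lag)
      expect_equal(r, 1, tolerance = 1e-9)
    }
  }
})

test_that("noise and jitter raise sample entropy, per the brute-force oracle", {
  quiet <- synth_gait_epoch(pure_params(), seed = 7)$acc_vt[1:500]
  noisy_p <- gait_signal_params(
    stride_frequency = 1,
    harmonic_amplitudes_even = list(vt = 1, ml = 0.4, ap = 1),
    harmonic_amplitudes_odd = list(vt = 0.5, ml = 0.8, ap = 0.4),
    asymmetry = 0, freq_jitter_sd = 0.02, noise_sd = 0.3
  )
  noisy <- synth_gait_epoch(noisy_p, seed = 7)$acc_vt[1:500]
  se_quiet <- sampen_brute(quiet, m = 5, r_abs = 0.3 * sd(quiet))
  se_noisy <- sampen_brute(noisy, m = 5, r_abs = 0.3 * sd(noisy))
  expect_gt(se_noisy, se_quiet)
})

test_that("invalid signal parameters are rejected", {
  expect_error(gait_signal_params(sample_rate = -1), "positive")
  expect_error(gait_signal_params(epoch_duration = 0), "positive")
  expect_error(gait_signal_params(sample_rate = 100, epoch_duration = 10.005),
               "integer sample count")
  expect_error(gait_signal_params(asymmetry = -0.1), "asymmetry")
})

test_that("cohorts have the requested shape and are bit-reproducible", {
  cp <- cohort_params(n_participants = 2, epochs_per_participant = 10, seed = 4)
  ch <- synth_cohort(cp)
  expect_equal(nrow(ch$cohort), 2)
  expect_equal(nrow(ch$epoch_features), 20)
  expect_equal(unname(table(ch$epoch_features$participant_id)), c(10L, 10L),
               ignore_attr = TRUE)

  cp2 <- cohort_params(n_participants = 25, epochs_per_participant = 12, seed = 8)
  a <- synth_cohort(cp2)
  b <- synth_cohort(cp2)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$epoch_features, b$epoch_features)
})

test_that("an intercept-only outcome model hits the target faller fraction", {
  cp <- cohort_params(
    outcome_coefficients = setNames(numeric(0), character(0)),
    intercept = qlogis(0.35), seed = 21
  )
  ch <- synth_cohort(cp)
  # binomial error at n = 202: 3 SE ~ 0.10
  expect_lt(abs(mean(ch$cohort$faller) - 0.35), 0.10)
})

test_that("mean generative fall probability matches realized fraction", {
  for (s in 1:4) {
    ch <- synth_cohort(cohort_params(n_participants = 202, seed = 100 + s))
    p <- ch$ground_truth$p_fall
    se3 <- 3 * sqrt(mean(p * (1 - p)) / length(p))
    expect_lt(abs(mean(p) - mean(ch$cohort$faller)), se3 + 1e-12)
  }
})

test_that("a positive generative coefficient is recovered in sign by the scan", {
  cp <- cohort_params(
    n_participants = 400, epochs_per_participant = 15,
    outcome_coefficients = c(sample_entropy_vt__p50 = 0.5),
    seed = 31
  )
  ch <- synth_cohort(cp)
  sc <- univariate_scan(ch$cohort)
  row <- sc[sc$term == "sample_entropy_vt__p50", ]
  expect_gt(row$B, 0)
  expect_lt(row$p, 0.05)
})

test_that("unknown outcome coefficient names raise a configuration error", {
  cp <- cohort_params(
    n_participants = 20, epochs_per_participant = 10,
    outcome_coefficients = c(not_a_feature = 1), seed = 1
  )
  expect_error(synth_cohort(cp), class = "gaitrisk_config_error")
})

test_that("two generated weeks share latents; ICC endpoints behave", {
  # no epoch noise: the two weeks are identical, ICC = 1
  cp0 <- cohort_params(
    n_participants = 30, epochs_per_participant = 10,
    epoch_noise_scale = 0, seed = 41
  )
  wk <- synth_two_weeks(cp0)
  icc <- icc_between_weeks(wk$week1$cohort, wk$week2$cohort)
  expect_true(all(abs(icc$icc - 1) < 1e-9, na.rm = TRUE))

  # no between-participant signal (quality variance 0 and all gait variance
  # routed through the quality factor): ICC near zero
  cp1 <- cohort_params(
    n_participants = 50, epochs_per_participant = 10,
    quality_sd = 0, quality_share = 1, dispersion_sdlog = 0, seed = 42
  )
  wk1 <- synth_two_weeks(cp1)
  icc1 <- icc_between_weeks(wk1$week1$cohort, wk1$week2$cohort)
  expect_lt(median(abs(icc1$icc), na.rm = TRUE), 0.2)
})
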