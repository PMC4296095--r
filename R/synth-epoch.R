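#' Parameters of the synthetic gait-signal model
#'
#' The generator models trunk acceleration during steady walking as a sum of
#' stride harmonics per axis with phase-continuous stride-frequency wander
#' plus white noise. Vertical (VT) and anterior-posterior (AP) axes carry
#' their symmetric content at even stride harmonics (step frequency and
#' multiples); the mediolateral (ML) axis is fundamentally periodic at stride
#' frequency (odd harmonics). The `asymmetry` parameter scales the
#' "wrong-parity" harmonics on each axis (odd on VT/AP, even on ML), so
#' `asymmetry = 0` with no noise and no jitter gives a perfectly
#' step-symmetric, exactly periodic signal.
#'
#' @param stride_frequency Stride frequency in Hz (typically 0.8-1.2).
#' @param harmonic_amplitudes_even Per-axis amplitudes (m/s^2) at even stride
#'   harmonics `2f, 4f, ...`; a named list with elements `vt`, `ml`, `ap`.
#' @param harmonic_amplitudes_odd Per-axis amplitudes at odd stride harmonics
#'   `1f, 3f, ...`.
#' @param asymmetry Dimensionless, `>= 0`; scales odd harmonics on VT/AP and
#'   even harmonics on ML.
#' @param freq_jitter_sd Stationary SD (Hz) of the Ornstein-Uhlenbeck wander
#'   of the instantaneous stride frequency (relaxation time 1 s).
#' @param noise_sd SD of additive white noise, m/s^2.
#' @param epoch_duration Epoch length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @return A `gait_signal_params` object.
#' @examples
#' p <- gait_signal_params(stride_frequency = 1, noise_sd = 0.2)
#' ep <- synth_gait_epoch(p, seed = 1)
#' @export
gait_signal_params <- function(stride_frequency = 1.0,
                               harmonic_amplitudes_even = list(
                                 vt = c(1.58, 0.5, 0.2, 0.08),
                                 ml = c(0.40, 0.15, 0.06, 0.02),
                                 ap = c(1.00, 0.30, 0.12, 0.05)
                               ),
                               harmonic_amplitudes_odd = list(
                                 vt = c(0.50, 0.20, 0.08, 0.03),
                                 ml = c(0.80, 0.25, 0.10, 0.04),
                                 ap = c(0.40, 0.15, 0.06, 0.02)
                               ),
                               asymmetry = 0.25,
                               freq_jitter_sd = 0.015,
                               noise_sd = 0.15,
                               epoch_duration = 10,
                               sample_rate = 100) {
  if (sample_rate <= 0 || epoch_duration <= 0) {
    abort("sample_rate and epoch_duration must be positive")
  }
  n <- sample_rate * epoch_duration
  if (abs(n - round(n)) > 1e-9) {
    abort("sample_rate * epoch_duration must be an integer sample count")
  }
  amps <- c(unlist(harmonic_amplitudes_even), unlist(harmonic_amplitudes_odd))
  if (any(amps < 0)) abort("harmonic amplitudes must be >= 0")
  if (asymmetry < 0) abort("asymmetry must be >= 0")
  if (freq_jitter_sd < 0 || noise_sd < 0) abort("noise SDs must be >= 0")
  if (stride_frequency <= 0) abort("stride_frequency must be positive")
  structure(
    list(
      stride_frequency = stride_frequency,
      harmonic_amplitudes_even = harmonic_amplitudes_even,
      harmonic_amplitudes_odd = harmonic_amplitudes_odd,
      asymmetry = asymmetry,
      freq_jitter_sd = freq_jitter_sd,
      noise_sd = noise_sd,
      epoch_duration = epoch_duration,
      sample_rate = sample_rate
    ),
    class = "gait_signal_params"
  )
}

#' Synthesize one gait-like acceleration epoch
#'
#' Deterministic given `params` and `seed`. When all stochastic terms
#' (`noise_sd`, `freq_jitter_sd`) are zero the output is exactly periodic
#' with period `1/stride_frequency` and contains no random draws, so any two
#' seeds give identical epochs.
#'
#' @param params A [gait_signal_params()] object.
#' @param seed Integer seed for the epoch's noise and jitter draws.
#' @return An `accel_epoch`: a tibble with columns `time_s`, `acc_vt`,
#'   `acc_ml`, `acc_ap` and a `sample_rate` attribute.
#' @export
synth_gait_epoch <- function(params, seed = 1L) {
  stopifnot(inherits(params, "gait_signal_params"))
  fs <- params$sample_rate
  n <- as.integer(round(fs * params$epoch_duration))
  dt <- 1 / fs
  f0 <- params$stride_frequency

  f_inst <- rep(f0, n)
  noise <- list(vt = numeric(n), ml = numeric(n), ap = numeric(n))
  needs_rng <- params$freq_jitter_sd > 0 || params$noise_sd > 0
  if (needs_rng) {
    withr::with_seed(as.integer(seed), {
      if (params$freq_jitter_sd > 0) {
        # Ornstein-Uhlenbeck wander, relaxation time 1 s, stationary SD as set
        tau <- 1
        a <- exp(-dt / tau)
        b <- params$freq_jitter_sd * sqrt(1 - a^2)
        dev <- numeric(n)
        dev[1] <- rnorm(1, 0, params$freq_jitter_sd)
        eps <- rnorm(n - 1)
        for (i in 2:n) dev[i] <- a * dev[i - 1] + b * eps[i - 1]
        f_inst <- pmax(0.05, f0 + dev)
      }
      if (params$noise_sd > 0) {
        noise <- list(
          vt = rnorm(n, 0, params$noise_sd),
          ml = rnorm(n, 0, params$noise_sd),
          ap = rnorm(n, 0, params$noise_sd)
        )
      }
    })
  }

  # phase-continuous stride phase (radians); t = 0 starts at phase 0
  phase <- 2 * pi * cumsum(c(0, f_inst[-n])) * dt

  series <- function(amps_even, amps_odd, even_scale, odd_scale) {
    out <- numeric(n)
    for (j in seq_along(amps_even)) {
      if (amps_even[j] > 0 && even_scale > 0) {
        out <- out + even_scale * amps_even[j] * sin(2 * j * phase)
      }
    }
    for (j in seq_along(amps_odd)) {
      if (amps_odd[j] > 0 && odd_scale > 0) {
        out <- out + odd_scale * amps_odd[j] * sin((2 * j - 1) * phase)
      }
    }
    out
  }

  asym <- params$asymmetry
  ev <- params$harmonic_amplitudes_even
  od <- params$harmonic_amplitudes_odd
  epoch <- tibble::tibble(
    time_s = (0:(n - 1)) * dt,
    acc_vt = series(ev$vt, od$vt, 1, asym) + noise$vt,
    acc_ml = series(ev$ml, od$ml, asym, 1) + noise$ml,
    acc_ap = series(ev$ap, od$ap, 1, asym) + noise$ap
  )
  new_accel_epoch(epoch, fs)
}

new_accel_epoch <- function(df, sample_rate) {
  structure(df,
    sample_rate = sample_rate,
    class = c("accel_epoch", class(tibble::tibble()))
  )
}

#' Validate and construct an acceleration epoch
#'
#' Checks the device contract: equal-length axes with no missing samples, a
#' sample count matching `sample_rate * duration`, and accelerations within
#' the +-6 g sampling range.
#'
#' @param df Data frame with columns `time_s`, `acc_vt`, `acc_ml`, `acc_ap`.
#' @param sample_rate Sampling rate in Hz.
#' @param duration Expected epoch duration in seconds.
#' @return An `accel_epoch` tibble, or an error describing the violation.
#' @export
as_accel_epoch <- function(df, sample_rate = 100, duration = 10) {
  need <- c("time_s", "acc_vt", "acc_ml", "acc_ap")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("epoch is missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "gaitrisk_schema_error")
  }
  n_expected <- round(sample_rate * duration)
  if (nrow(df) != n_expected) {
    abort(sprintf("epoch has %d samples, expected %d", nrow(df), n_expected),
          class = "gaitrisk_length_error")
  }
  acc <- as.matrix(df[, c("acc_vt", "acc_ml", "acc_ap")])
  if (anyNA(acc)) {
    abort("epoch contains missing samples", class = "gaitrisk_schema_error")
  }
  g6 <- 6 * 9.80665
  if (any(abs(acc) > g6)) {
    abort("epoch exceeds the +-6 g sampling range", class = "gaitrisk_range_error")
  }
  new_accel_epoch(tibble::as_tibble(df[, need]), sample_rate)
}

epoch_sample_rate <- function(epoch) {
  attr(epoch, "sample_rate") %||% (1 / stats::median(diff(epoch$time_s)))
}
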