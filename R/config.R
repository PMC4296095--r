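#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline in one nested list:
#' sample-entropy settings (`m = 5` points, tolerance `r = 0.3` of the
#' per-epoch SD), Welch spectral settings, the stride-frequency search band,
#' local-dynamic-stability embedding, the inverted-pendulum leg length, the
#' running-epoch filter (stride time < 0.8 s or vertical RMS > 5 m/s^2),
#' week-summary percentiles, stepwise-selection thresholds (entry alpha .05,
#' Spearman collinearity cap .7) and the permutation-test defaults
#' (1000 permutations).
#'
#' @param ... Named overrides for any top-level entry; the override list is
#'   merged element-wise into the defaults.
#' @return A `gait_config` object (a nested named list).
#' @examples
#' cfg <- gait_config(stepwise = list(alpha = 0.01))
#' cfg$stepwise$alpha
#' @export
gait_config <- function(...) {
  defaults <- list(
    sampen = list(m = 5L, r = 0.3),
    spectral = list(
      window_s = 10, overlap = 0.5, pad = 4L,
      harmonics_hr = 20L, harmonics_ih = 5L,
      lowfreq_cutoff_vt = 0.7, lowfreq_cutoff_ml = 10, lowfreq_cutoff_ap = 0.7,
      total_band_min = 0.1, hr_cap = 100
    ),
    stride = list(band = c(0.4, 1.6), min_autocorr = 0.25),
    freq_var = list(window_s = 2.5, overlap = 0.5, band = c(0.5, 3.5)),
    lds = list(dim = 5L, delay = 10L, fit_fraction_stride = 0.5),
    speed = list(leg_length = 0.9, highpass_hz = 0.5),
    running_filter = list(min_stride_time = 0.8, max_vt_rms = 5),
    summary = list(min_epochs = 10L, probs = c(0.1, 0.5, 0.9)),
    stepwise = list(alpha = 0.05, rho_max = 0.7),
    permutation = list(n_permutations = 1000L, small_sample_correction = FALSE)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    abort(paste0("Unknown gait_config entries: ", paste(bad, collapse = ", ")))
  }
  for (nm in names(overrides)) {
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], as.list(overrides[[nm]]))
  }
  structure(defaults, class = "gait_config")
}

#' Read or write a configuration as YAML
#'
#' The YAML round trip is value-exact: `read_gait_config(write_gait_config(x))`
#' reproduces `x`.
#'
#' @param config A `gait_config` object.
#' @param path File path of the YAML document.
#' @return `read_gait_config` returns a `gait_config`; `write_gait_config`
#'   returns `path` invisibly.
#' @export
write_gait_config <- function(config, path) {
  stopifnot(inherits(config, "gait_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_gait_config
#' @export
read_gait_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- gait_config()
  for (nm in intersect(names(raw), names(cfg))) {
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], raw[[nm]])
  }
  # vector-valued leaves come back from YAML as lists; restore them
  cfg$stride$band <- as.numeric(unlist(cfg$stride$band))
  cfg$freq_var$band <- as.numeric(unlist(cfg$freq_var$band))
  cfg$summary$probs <- as.numeric(unlist(cfg$summary$probs))
  cfg
}
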