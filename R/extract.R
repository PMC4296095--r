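axis_cols <- c(vt = "acc_vt", ml = "acc_ml", ap = "acc_ap")

axis_feature_stems <- c(
  "frequency_variability", "stride_regularity", "rms",
  "low_frequency_percentage", "index_of_harmonicity", "harmonic_ratio",
  "local_dynamic_stability", "sample_entropy", "dominant_frequency_amplitude"
)

#' Names of the 30 gait characteristics
#'
#' Three whole-epoch characteristics (gait speed, speed variability, stride
#' frequency) plus nine characteristics per axis (VT, ML, AP).
#'
#' @return Character vector of length 30.
#' @export
gait_feature_names <- function() {
  c(
    "gait_speed", "speed_variability", "stride_frequency",
    as.vector(t(outer(axis_feature_stems, c("vt", "ml", "ap"), paste, sep = "_")))
  )
}

#' Extract all 30 gait characteristics from one epoch
#'
#' Pure function of `(epoch, config)`. Each axis is mean-centered before
#' analysis (the generator produces gravity-removed dynamic acceleration; no
#' tilt rotation is applied). Characteristics that cannot be estimated — no
#' detectable stride periodicity, a degenerate constant axis, no matching
#' sample-entropy templates — are returned as `NA` and the reasons collected
#' in the `qc_flags` column rather than absorbed as sentinel numbers, so that
#' downstream percentile summaries skip them.
#'
#' @param epoch An `accel_epoch` (see [synth_gait_epoch()], [as_accel_epoch()]).
#' @param config A [gait_config()].
#' @return A one-row tibble with the 30 characteristics, the auxiliary
#'   `stride_time` (s, `1/stride_frequency`, used by the running filter), and
#'   a `qc_flags` string (`""` when clean).
#' @examples
#' ep <- synth_gait_epoch(gait_signal_params(), seed = 2)
#' extract_features(ep)
#' @export
extract_features <- function(epoch, config = gait_config()) {
  fs <- epoch_sample_rate(epoch)
  flags <- character(0)
  out <- setNames(
    as.list(rep(NA_real_, length(gait_feature_names()))),
    gait_feature_names()
  )

  sig <- lapply(axis_cols, function(cl) {
    x <- epoch[[cl]]
    x - mean(x)
  })

  # RMS is defined for any signal
  for (ax in names(sig)) out[[paste0("rms_", ax)]] <- rms(sig[[ax]])

  f_s <- stride_frequency(sig$vt, fs,
    band = config$stride$band,
    min_autocorr = config$stride$min_autocorr
  )
  if (!is.finite(f_s)) {
    flags <- c(flags, "stride_undefined")
  } else {
    out$stride_frequency <- f_s
  }

  sp <- config$spectral
  cutoffs <- c(
    vt = sp$lowfreq_cutoff_vt, ml = sp$lowfreq_cutoff_ml,
    ap = sp$lowfreq_cutoff_ap
  )

  for (ax in names(sig)) {
    x <- sig[[ax]]
    if (sd(x) == 0) {
      flags <- c(flags, paste0("degenerate_", ax))
      next
    }
    # fundamental convention: step frequency on VT/AP, stride frequency on ML
    fund <- if (is.finite(f_s)) {
      if (ax == "ml") f_s else 2 * f_s
    } else {
      NA_real_
    }

    if (is.finite(f_s)) {
      out[[paste0("stride_regularity_", ax)]] <-
        stride_regularity(x, fs, f_s)
      hr <- harmonic_ratio(x, fs, f_s,
        axis = ax,
        n_harmonics = sp$harmonics_hr, cap = sp$hr_cap
      )
      if (isTRUE(attr(hr, "capped"))) flags <- c(flags, paste0("hr_capped_", ax))
      out[[paste0("harmonic_ratio_", ax)]] <- as.numeric(hr)
      out[[paste0("index_of_harmonicity_", ax)]] <-
        index_of_harmonicity(x, fs, fund, n_harmonics = sp$harmonics_ih)
      out[[paste0("local_dynamic_stability_", ax)]] <-
        local_dynamic_stability(x, fs, f_s,
          dim = config$lds$dim, delay = config$lds$delay,
          fit_fraction_stride = config$lds$fit_fraction_stride
        )
      out[[paste0("dominant_frequency_amplitude_", ax)]] <-
        dominant_frequency_amplitude(x, fs, fund)
    }
    out[[paste0("low_frequency_percentage_", ax)]] <-
      low_frequency_percentage(x, fs, cutoffs[[ax]],
        window_s = sp$window_s, overlap = sp$overlap,
        band_min = sp$total_band_min
      )
    out[[paste0("frequency_variability_", ax)]] <-
      frequency_variability(x, fs,
        band = config$freq_var$band,
        window_s = config$freq_var$window_s,
        overlap = config$freq_var$overlap
      )
    se <- sample_entropy(x, m = config$sampen$m, r = config$sampen$r)
    if (is.na(se)) flags <- c(flags, paste0("sampen_undefined_", ax))
    out[[paste0("sample_entropy_", ax)]] <- se
  }

  if (is.finite(f_s)) {
    sv <- gait_speed_and_variability(epoch$acc_vt, fs, f_s,
      leg_length = config$speed$leg_length,
      highpass_hz = config$speed$highpass_hz
    )
    out$gait_speed <- sv$speed
    out$speed_variability <- sv$variability
  }

  res <- tibble::as_tibble(out)
  res$stride_time <- if (is.finite(f_s)) 1 / f_s else NA_real_
  res$qc_flags <- paste(unique(flags), collapse = ";")
  res
}

#' Extract features for every epoch of a cohort
#'
#' @param epochs Either a list of `accel_epoch` objects or a long tibble with
#'   columns `participant_id`, `epoch_id`, `time_s`, `acc_vt`, `acc_ml`,
#'   `acc_ap` (the on-disk epoch schema).
#' @param config A [gait_config()].
#' @param sample_rate Sampling rate used when `epochs` is a long tibble.
#' @return A tibble with one row per epoch: `participant_id`, `epoch_id`, the
#'   30 characteristics, `stride_time` and `qc_flags`.
#' @export
extract_cohort_features <- function(epochs, config = gait_config(),
                                    sample_rate = 100) {
  if (is.data.frame(epochs)) {
    epochs <- epochs |>
      dplyr::group_by(.data$participant_id, .data$epoch_id) |>
      dplyr::group_split()
    rows <- purrr::map(epochs, function(df) {
      ep <- new_accel_epoch(df[, c("time_s", "acc_vt", "acc_ml", "acc_ap")],
                            sample_rate)
      feats <- extract_features(ep, config)
      dplyr::bind_cols(
        tibble::tibble(
          participant_id = df$participant_id[1],
          epoch_id = df$epoch_id[1]
        ),
        feats
      )
    })
    return(dplyr::bind_rows(rows))
  }
  rows <- purrr::imap(epochs, function(ep, i) {
    feats <- extract_features(ep, config)
    pid <- attr(ep, "participant_id") %||% NA_character_
    eid <- attr(ep, "epoch_id") %||% i
    dplyr::bind_cols(tibble::tibble(participant_id = pid, epoch_id = eid), feats)
  })
  dplyr::bind_rows(rows)
}
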