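#' Generative catalog of the gait characteristics
#'
#' Plausible population baselines for the 30 characteristics, used by the
#' feature-level cohort generator: per-characteristic baseline mean,
#' between-participant SD, within-participant (epoch-to-epoch) SD, and the
#' sign with which the characteristic loads on the latent gait-quality
#' scalar (+1 improves with quality: speed, regularity, symmetry; -1 worsens:
#' entropy, divergence, variability, low-frequency content).
#'
#' @return A tibble with columns `feature`, `baseline`, `between_sd`,
#'   `epoch_sd`, `quality_sign`.
#' @export
gait_feature_catalog <- function() {
  tribble_rows <- list(
    c("gait_speed", 1.10, 0.15, 0.10, 1),
    c("speed_variability", 0.10, 0.030, 0.030, -1),
    c("stride_frequency", 1.00, 0.060, 0.030, 1),
    c("frequency_variability_vt", 0.030, 0.010, 0.010, -1),
    c("frequency_variability_ml", 0.035, 0.011, 0.011, -1),
    c("frequency_variability_ap", 0.032, 0.010, 0.010, -1),
    c("stride_regularity_vt", 0.85, 0.060, 0.060, 1),
    c("stride_regularity_ml", 0.70, 0.080, 0.080, 1),
    c("stride_regularity_ap", 0.80, 0.070, 0.070, 1),
    c("rms_vt", 2.20, 0.50, 0.40, 1),
    c("rms_ml", 1.50, 0.40, 0.35, 1),
    c("rms_ap", 1.80, 0.45, 0.40, 1),
    c("low_frequency_percentage_vt", 6.0, 3.0, 2.0, -1),
    c("low_frequency_percentage_ml", 55.0, 10.0, 8.0, -1),
    c("low_frequency_percentage_ap", 8.0, 3.0, 2.0, -1),
    c("index_of_harmonicity_vt", 0.80, 0.080, 0.070, 1),
    c("index_of_harmonicity_ml", 0.60, 0.100, 0.090, 1),
    c("index_of_harmonicity_ap", 0.75, 0.090, 0.080, 1),
    c("harmonic_ratio_vt", 2.20, 0.50, 0.45, 1),
    c("harmonic_ratio_ml", 2.00, 0.45, 0.42, 1),
    c("harmonic_ratio_ap", 2.10, 0.48, 0.44, 1),
    c("local_dynamic_stability_vt", 1.30, 0.25, 0.25, -1),
    c("local_dynamic_stability_ml", 1.50, 0.28, 0.28, -1),
    c("local_dynamic_stability_ap", 1.40, 0.26, 0.26, -1),
    c("sample_entropy_vt", 0.20, 0.060, 0.050, -1),
    c("sample_entropy_ml", 0.25, 0.070, 0.060, -1),
    c("sample_entropy_ap", 0.22, 0.065, 0.055, -1),
    c("dominant_frequency_amplitude_vt", 1.50, 0.35, 0.30, 1),
    c("dominant_frequency_amplitude_ml", 0.80, 0.22, 0.20, 1),
    c("dominant_frequency_amplitude_ap", 1.10, 0.28, 0.25, 1)
  )
  tibble::tibble(
    feature = vapply(tribble_rows, `[`, character(1), 1),
    baseline = as.numeric(vapply(tribble_rows, `[`, character(1), 2)),
    between_sd = as.numeric(vapply(tribble_rows, `[`, character(1), 3)),
    epoch_sd = as.numeric(vapply(tribble_rows, `[`, character(1), 4)),
    quality_sign = as.numeric(vapply(tribble_rows, `[`, character(1), 5))
  )
}

activity_names <- function() {
  c(
    "lying_duration", "sitting_duration", "standing_duration",
    "locomotion_duration", "shuffling_duration", "n_transitions", "n_steps"
  )
}

default_outcome_coefficients <- function() {
  c(
    fall_history = 0.55,
    gds_score = 0.45,
    lying_duration = -0.40,
    sample_entropy_vt__p50 = 0.41,
    low_frequency_percentage_vt__p50 = 0.38,
    harmonic_ratio_vt__p50 = -0.43
  )
}

#' Cohort-generation parameters
#'
#' Describes a synthetic cohort shaped like the study population: ~202
#' community-dwelling older adults wearing a trunk accelerometer for a week,
#' with roughly 35% fallers (70/202) over 6 months of follow-up. Each
#' participant carries a latent gait-quality scalar (standard normal) that
#' drives all gait characteristics, and a lognormal epoch-to-epoch dispersion
#' scalar that makes the spread between a participant's good and bad walking
#' epochs — hence the difference between their percentile extremes and their
#' median — a participant-level trait. The fall outcome is drawn from a
#' logistic model on the z-scaled cohort-table columns, so the generative
#' coefficients are recoverable by the univariate scan.
#'
#' @param n_participants Number of participants.
#' @param faller_fraction_target Target marginal faller fraction; sets the
#'   default intercept `qlogis(faller_fraction_target)`.
#' @param epochs_per_participant Number of 10-s walking epochs per week
#'   (desk-scale stand-in for a full week of walking; must be >= 10 so
#'   percentiles have support).
#' @param outcome_coefficients Named numeric vector of log-odds per SD on the
#'   z-scale. Names must be cohort-table columns: questionnaire
#'   (`fall_history`, `gds_score`), activities (see [activity_names()]), or
#'   feature percentiles (`<feature>__p10/__p50/__p90`). Defaults mirror the
#'   magnitudes of the significant univariate associations reported for
#'   cohorts of this kind.
#' @param intercept Intercept of the outcome model on the logit scale.
#' @param dispersion_sdlog SD (log scale) of the per-participant epoch
#'   dispersion scalar.
#' @param quality_sd SD of the latent gait-quality scalar (0 removes all
#'   between-participant gait differences).
#' @param quality_share Fraction of each characteristic's between-participant
#'   variance carried by the shared quality factor; the remainder is
#'   characteristic-specific (a one-factor covariance structure, giving
#'   moderate positive correlations between quality-aligned characteristics
#'   rather than a degenerate rank-one cohort).
#' @param epoch_noise_scale Multiplier on all epoch-level noise terms (0
#'   makes every epoch of a participant identical, so two generated weeks
#'   agree exactly).
#' @param questionnaire_model,activity_model Named lists of distribution
#'   settings for the questionnaire and activity columns.
#' @param mode `"feature"` draws per-epoch gait-feature rows directly from
#'   the generative model (fast; the default for cohort-scale simulation);
#'   `"signal"` synthesizes raw acceleration epochs and closes the loop
#'   through [extract_features()].
#' @param seed Integer seed; the cohort is bit-reproducible given the seed.
#' @return A `cohort_params` object.
#' @export
cohort_params <- function(n_participants = 202L,
                          faller_fraction_target = 0.35,
                          epochs_per_participant = 50L,
                          outcome_coefficients = default_outcome_coefficients(),
                          intercept = qlogis(faller_fraction_target),
                          dispersion_sdlog = 0.5,
                          quality_sd = 1,
                          quality_share = 0.4,
                          epoch_noise_scale = 1,
                          questionnaire_model = list(
                            fall_history_prob = 0.30,
                            gds_mean = 5, gds_sd = 4, gds_max = 30
                          ),
                          activity_model = list(
                            lying_duration = c(9, 1.2),
                            sitting_duration = c(9, 1.5),
                            standing_duration = c(3, 1),
                            locomotion_duration = c(1.5, 0.5),
                            shuffling_duration = c(0.3, 0.15),
                            n_transitions = c(55, 15),
                            n_steps = c(7000, 2500)
                          ),
                          mode = c("feature", "signal"),
                          seed = 1L) {
  if (n_participants < 2) abort("n_participants must be >= 2")
  if (epochs_per_participant < 10) {
    abort("epochs_per_participant must be >= 10 (percentiles need support)")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      faller_fraction_target = faller_fraction_target,
      epochs_per_participant = as.integer(epochs_per_participant),
      outcome_coefficients = outcome_coefficients,
      intercept = intercept,
      dispersion_sdlog = dispersion_sdlog,
      quality_sd = quality_sd,
      quality_share = quality_share,
      epoch_noise_scale = epoch_noise_scale,
      questionnaire_model = questionnaire_model,
      activity_model = activity_model,
      mode = match.arg(mode),
      seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
}

truncated_normal <- function(n, mean, sd, lower = 0, upper = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lower), upper)
}

# Draw questionnaire + activity tables and participant latents. The gait
# profile of participant i is a one-factor model: a shared quality scalar
# plus characteristic-specific between-participant deviations (`unique`,
# an n x 30 matrix), both stable traits shared across measurement weeks.
draw_participant_level <- function(params) {
  n <- params$n_participants
  qm <- params$questionnaire_model
  am <- params$activity_model
  acts <- lapply(activity_names(), function(nm) {
    truncated_normal(n, am[[nm]][1], am[[nm]][2])
  })
  names(acts) <- activity_names()
  info <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    fall_history = rbinom(n, 1, qm$fall_history_prob),
    gds_score = round(truncated_normal(n, qm$gds_mean, qm$gds_sd, 0, qm$gds_max)),
    !!!acts,
    quality = rnorm(n, 0, params$quality_sd),
    dispersion = exp(rnorm(n, -params$dispersion_sdlog^2 / 2,
                           params$dispersion_sdlog))
  )
  cat_tbl <- gait_feature_catalog()
  unique_sd <- cat_tbl$between_sd * sqrt(1 - params$quality_share)
  unique <- matrix(rnorm(n * nrow(cat_tbl)), nrow = n) %*% diag(unique_sd)
  colnames(unique) <- cat_tbl$feature
  list(info = info, unique = unique)
}

# Feature-mode epoch table: each epoch row is the participant mean profile
# plus dispersion-scaled epoch noise.
draw_feature_epochs <- function(latents, params) {
  cat_tbl <- gait_feature_catalog()
  info <- latents$info
  lambda <- cat_tbl$between_sd * sqrt(params$quality_share)
  n_ep <- params$epochs_per_participant
  rows <- purrr::map(seq_len(nrow(info)), function(i) {
    mu <- cat_tbl$baseline + cat_tbl$quality_sign * lambda * info$quality[i] +
      latents$unique[i, ]
    eps <- matrix(rnorm(n_ep * nrow(cat_tbl)), nrow = n_ep)
    vals <- sweep(eps, 2,
                  params$epoch_noise_scale * info$dispersion[i] * cat_tbl$epoch_sd,
                  `*`)
    vals <- sweep(vals, 2, mu, `+`)
    colnames(vals) <- cat_tbl$feature
    out <- tibble::as_tibble(vals)
    out$stride_frequency <- pmax(out$stride_frequency, 0.3)
    out$participant_id <- info$participant_id[i]
    out$epoch_id <- seq_len(n_ep)
    out
  })
  epochs <- dplyr::bind_rows(rows)
  epochs$stride_time <- 1 / epochs$stride_frequency
  epochs$qc_flags <- ""
  dplyr::relocate(epochs, "participant_id", "epoch_id")
}

# Signal-mode: map per-epoch quality into signal parameters, synthesize and
# extract. Worse quality = more noise, more jitter, more asymmetry, smaller
# vertical excursion (slower gait).
quality_to_signal_params <- function(q, f_stride, noise_scale = 1) {
  h <- pmax(0.005, 0.020 * (1 + 0.15 * q)) # vertical excursion, m
  a1 <- (2 * pi * 2 * f_stride)^2 * h / 2 # puts excursion h into VT
  gait_signal_params(
    stride_frequency = f_stride,
    harmonic_amplitudes_even = list(
      vt = a1 * c(1, 0.3, 0.12, 0.05),
      ml = 0.25 * a1 * c(1, 0.35, 0.15, 0.05),
      ap = 0.6 * a1 * c(1, 0.3, 0.12, 0.05)
    ),
    harmonic_amplitudes_odd = list(
      vt = 0.3 * a1 * c(1, 0.4, 0.15, 0.06),
      ml = 0.5 * a1 * c(1, 0.3, 0.12, 0.05),
      ap = 0.4 * a1 * c(1, 0.35, 0.15, 0.06)
    ),
    asymmetry = pmax(0, 0.25 * exp(-0.5 * q)),
    freq_jitter_sd = noise_scale * 0.015 * exp(-0.4 * q),
    noise_sd = noise_scale * 0.20 * exp(-0.4 * q)
  )
}

draw_signal_epochs <- function(latents, params, config) {
  info <- latents$info
  n_ep <- params$epochs_per_participant
  all_feats <- list()
  all_epochs <- list()
  k <- 0L
  for (i in seq_len(nrow(info))) {
    q_i <- info$quality[i]
    s_i <- info$dispersion[i]
    f_base <- pmin(1.4, pmax(0.6, 1 + 0.05 * q_i))
    ns <- params$epoch_noise_scale
    for (e in seq_len(n_ep)) {
      k <- k + 1L
      q_ie <- q_i + ns * s_i * 0.5 * rnorm(1)
      f_e <- pmin(1.55, pmax(0.45, f_base + ns * 0.02 * rnorm(1)))
      sp <- quality_to_signal_params(q_ie, f_e, noise_scale = ns)
      ep_seed <- sample.int(.Machine$integer.max, 1)
      ep <- synth_gait_epoch(sp, seed = ep_seed)
      feats <- extract_features(ep, config)
      feats$participant_id <- info$participant_id[i]
      feats$epoch_id <- e
      all_feats[[k]] <- feats
      ep_long <- tibble::as_tibble(ep)
      ep_long$participant_id <- info$participant_id[i]
      ep_long$epoch_id <- e
      all_epochs[[k]] <- ep_long
    }
  }
  list(
    features = dplyr::relocate(dplyr::bind_rows(all_feats),
                               "participant_id", "epoch_id"),
    epochs = dplyr::bind_rows(all_epochs)
  )
}

draw_outcome <- function(cohort, params) {
  coefs <- params$outcome_coefficients
  unknown <- setdiff(names(coefs), names(cohort))
  if (length(unknown)) {
    abort(
      paste0("outcome_coefficients reference unknown features: ",
             paste(unknown, collapse = ", ")),
      class = "gaitrisk_config_error"
    )
  }
  eta <- rep(params$intercept, nrow(cohort))
  for (nm in names(coefs)) {
    x <- cohort[[nm]]
    s <- sd(x, na.rm = TRUE)
    z <- if (is.na(s) || s == 0) {
      rep(0, length(x))
    } else {
      (x - mean(x, na.rm = TRUE)) / s
    }
    # participants without a defined summary contribute at baseline odds
    z[is.na(z)] <- 0
    eta <- eta + coefs[[nm]] * z
  }
  p <- plogis(eta)
  list(p = p, faller = rbinom(length(p), 1, p), linear_predictor = eta)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Builds the full study substrate: per-participant questionnaire data and
#' activity amounts, a week of per-epoch gait characteristics (drawn directly
#' in `"feature"` mode, or synthesized as raw acceleration epochs and
#' extracted in `"signal"` mode), week-level percentile summaries, and a fall
#' outcome drawn from a logistic model with known coefficients on the
#' z-scaled cohort columns.
#'
#' @param params A [cohort_params()] object.
#' @param config A [gait_config()] (filtering, summarization and — in signal
#'   mode — extraction settings).
#' @return A `gait_cohort` list with elements `cohort` (one row per
#'   participant: questionnaire, activities, `<feature>__p10/__p50/__p90`
#'   columns, `n_epochs_used`, `faller`), `epoch_features`, `epochs` (signal
#'   mode only), `ground_truth` (intercept, coefficients, latent quality and
#'   dispersion, per-participant fall probability) and `params`.
#' @examples
#' cp <- cohort_params(n_participants = 20, epochs_per_participant = 15, seed = 7)
#' ch <- synth_cohort(cp)
#' dplyr::count(ch$cohort, faller)
#' @export
synth_cohort <- function(params = cohort_params(), config = gait_config()) {
  withr::with_seed(params$seed, synth_cohort_impl(params, config))
}

synth_cohort_impl <- function(params, config, latents = NULL) {
  if (is.null(latents)) latents <- draw_participant_level(params)
  epochs_raw <- NULL
  if (params$mode == "feature") {
    epoch_features <- draw_feature_epochs(latents, params)
  } else {
    drawn <- draw_signal_epochs(latents, params, config)
    epoch_features <- drawn$features
    epochs_raw <- drawn$epochs
  }
  walking <- exclude_running(epoch_features,
    min_stride_time = config$running_filter$min_stride_time,
    max_vt_rms = config$running_filter$max_vt_rms
  )
  summaries <- summarize_percentiles(walking,
    min_epochs = config$summary$min_epochs,
    probs = config$summary$probs
  )
  cohort <- dplyr::left_join(
    dplyr::select(latents$info, -"quality", -"dispersion"),
    summaries,
    by = "participant_id"
  )
  out <- draw_outcome(cohort, params)
  cohort$faller <- out$faller
  structure(
    list(
      cohort = cohort,
      epoch_features = epoch_features,
      epochs = epochs_raw,
      ground_truth = list(
        intercept = params$intercept,
        coefficients = params$outcome_coefficients,
        latents = latents,
        p_fall = out$p,
        linear_predictor = out$linear_predictor
      ),
      params = params
    ),
    class = "gait_cohort"
  )
}

#' Generate two measurement weeks for the same cohort
#'
#' Both weeks share every participant's latent quality and dispersion (and
#' questionnaire/activity draws) but use fresh epoch-level randomness — the
#' substrate for between-week reliability (ICC) analyses.
#'
#' @inheritParams synth_cohort
#' @return A list with elements `week1` and `week2`, each a `gait_cohort`.
#'   The fall outcome is drawn once (in `week1`) and copied to `week2`.
#' @export
synth_two_weeks <- function(params = cohort_params(), config = gait_config()) {
  withr::with_seed(params$seed, {
    latents <- draw_participant_level(params)
    week1 <- synth_cohort_impl(params, config, latents = latents)
    week2 <- synth_cohort_impl(params, config, latents = latents)
    week2$cohort$faller <- week1$cohort$faller
    week2$ground_truth$p_fall <- week1$ground_truth$p_fall
    list(week1 = week1, week2 = week2)
  })
}
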