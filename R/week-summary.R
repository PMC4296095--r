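#' Exclude suspected running epochs
#'
#' Locomotion epochs suspected to reflect running — severe outliers for some
#' participants — are identified by a low stride time (< 0.8 s) and/or a high
#' vertical acceleration RMS (> 5 m/s^2) and discarded. Both inequalities are
#' strict, so boundary values are retained. Rows whose `stride_time` or
#' `rms_vt` is missing are retained (no evidence of running). Idempotent.
#'
#' @param features Per-epoch feature tibble containing `stride_time` (s) and
#'   `rms_vt` (m/s^2).
#' @param min_stride_time Stride-time threshold, s.
#' @param max_vt_rms Vertical RMS threshold, m/s^2.
#' @return The retained rows, with attributes `n_excluded` and `n_input`.
#' @examples
#' df <- tibble::tibble(stride_time = c(0.75, 0.9), rms_vt = c(4, 4))
#' exclude_running(df)
#' @export
exclude_running <- function(features, min_stride_time = 0.8, max_vt_rms = 5) {
  stopifnot(min_stride_time > 0, max_vt_rms > 0)
  stopifnot(all(c("stride_time", "rms_vt") %in% names(features)))
  running <- (features$stride_time < min_stride_time) |
    (features$rms_vt > max_vt_rms)
  running[is.na(running)] <- FALSE
  out <- features[!running, , drop = FALSE]
  attr(out, "n_excluded") <- sum(running)
  attr(out, "n_input") <- nrow(features)
  if (nrow(out) == 0) warn("running filter removed every epoch")
  out
}

#' Week-level percentile summaries per participant
#'
#' Summarizes each participant's retained walking epochs into the 10th, 50th
#' and 90th percentile of every gait characteristic, using the linear
#' interpolation percentile rule (R quantile type 7). Missing feature values
#' are skipped, and a characteristic with fewer than `min_epochs` defined
#' values for a participant is reported as missing rather than summarized.
#'
#' @param features Per-epoch feature tibble with a `participant_id` column
#'   (typically the output of [exclude_running()]).
#' @param min_epochs Minimum number of defined values required per
#'   participant and characteristic.
#' @param probs Percentile probabilities (default 0.1, 0.5, 0.9).
#' @param include_extremes Also report the raw per-week minimum and maximum
#'   (`__min`/`__max` columns), the unstable quantities the percentile
#'   extremes stand in for.
#' @param features_to_summarize Characteristic columns to summarize; defaults
#'   to [gait_feature_names()] present in the data.
#' @return One row per participant: `participant_id`, `n_epochs_used`, and
#'   `<feature>__p10`, `__p50`, `__p90` (and `__min`/`__max` on request).
#' @export
summarize_percentiles <- function(features, min_epochs = 10L,
                                  probs = c(0.1, 0.5, 0.9),
                                  include_extremes = FALSE,
                                  features_to_summarize = NULL) {
  stopifnot("participant_id" %in% names(features))
  cols <- features_to_summarize %||%
    intersect(gait_feature_names(), names(features))
  lab <- paste0("p", round(100 * probs))
  if (include_extremes) lab <- c(lab, "min", "max")
  n_stat <- length(lab)
  # inline type-7 quantile (linear interpolation between order statistics)
  summarize_one <- function(x) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < min_epochs) return(rep(NA_real_, n_stat))
    xs <- sort(x)
    h <- (n - 1) * probs + 1
    lo <- floor(h)
    q <- xs[lo] + (h - lo) * (xs[pmin(lo + 1, n)] - xs[lo])
    if (include_extremes) q <- c(q, xs[1], xs[n])
    q
  }
  idx <- split(seq_len(nrow(features)), features$participant_id)
  pieces <- lapply(cols, function(cl) {
    x <- features[[cl]]
    m <- t(vapply(idx, function(ii) summarize_one(x[ii]), numeric(n_stat)))
    colnames(m) <- paste0(cl, "__", lab)
    m
  })
  dplyr::bind_cols(
    tibble::tibble(
      participant_id = names(idx),
      n_epochs_used = unname(lengths(idx))
    ),
    tibble::as_tibble(do.call(cbind, pieces))
  )
}

# ICC(A,1): two-way random effects, absolute agreement, single measure,
# from the ANOVA mean squares of an n x k subjects-by-weeks table.
icc_a1 <- function(m) {
  m <- as.matrix(m)
  keep <- complete.cases(m)
  m <- m[keep, , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) return(NA_real_)
  mu <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - mu)^2) / (n - 1)
  msc <- n * sum((col_means - mu)^2) / (k - 1)
  resid <- m - outer(row_means, rep(1, k)) -
    outer(rep(1, n), col_means) + mu
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) return(if (msr == mse) NA_real_ else 1)
  (msr - mse) / denom
}

#' Between-week reliability of the percentile summaries
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation (ICC) per characteristic and percentile, between two
#' measurement weeks of the same participants. The study convention treats
#' ICC >= 0.7 as sufficiently reliable.
#'
#' @param week1,week2 Participant-level summary tibbles (as produced by
#'   [summarize_percentiles()]) for the two weeks; participants are matched
#'   by `participant_id`.
#' @return A tibble with columns `characteristic`, `percentile` (e.g. "p10",
#'   or "min"/"max" when present) and `icc`; `NA` with fewer than 3 shared
#'   participants.
#' @export
icc_between_weeks <- function(week1, week2) {
  shared <- intersect(week1$participant_id, week2$participant_id)
  w1 <- week1[match(shared, week1$participant_id), , drop = FALSE]
  w2 <- week2[match(shared, week2$participant_id), , drop = FALSE]
  cols <- grep("__", intersect(names(week1), names(week2)), value = TRUE)
  parts <- strsplit(cols, "__", fixed = TRUE)
  tibble::tibble(
    characteristic = vapply(parts, `[`, character(1), 1),
    percentile = vapply(parts, `[`, character(1), 2),
    icc = vapply(cols, function(cl) icc_a1(cbind(w1[[cl]], w2[[cl]])),
                 numeric(1), USE.NAMES = FALSE)
  )
}
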