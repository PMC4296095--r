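#' Write and read acceleration epochs as CSV
#'
#' The on-disk schema is a long-format CSV with columns `participant_id`,
#' `epoch_id`, `time_s`, `acc_vt`, `acc_ml`, `acc_ap` (SI units, m/s^2).
#' `read_epochs()` validates each epoch against the device contract — the
#' axis columns present, exactly `sample_rate * duration` samples, no missing
#' values, accelerations within +-6 g — and rejects violating epochs
#' individually with a reason, rather than failing the whole file.
#'
#' @param epochs Long tibble of epochs (e.g. `synth_cohort(...)$epochs`).
#' @param path CSV file path.
#' @return `write_epochs()` returns `path` invisibly.
#' @export
write_epochs <- function(epochs, path) {
  cols <- c("participant_id", "epoch_id", "time_s", "acc_vt", "acc_ml", "acc_ap")
  stopifnot(all(cols %in% names(epochs)))
  readr::write_csv(epochs[, cols], path)
  invisible(path)
}

#' @rdname write_epochs
#' @param path CSV file path.
#' @param sample_rate Expected sampling rate, Hz.
#' @param duration Expected epoch duration, s.
#' @return `read_epochs()` returns a list with `epochs` (a list of validated
#'   `accel_epoch` objects carrying `participant_id`/`epoch_id` attributes)
#'   and `rejected` (a tibble of epoch ids with rejection reasons).
#' @export
read_epochs <- function(path, sample_rate = 100, duration = 10) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "acc_vt", "acc_ml", "acc_ap")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(
      paste0("epoch file is missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "gaitrisk_schema_error"
    )
  }
  if (!"participant_id" %in% names(df)) df$participant_id <- "P001"
  if (!"epoch_id" %in% names(df)) df$epoch_id <- 1L
  groups <- df |>
    dplyr::group_by(.data$participant_id, .data$epoch_id) |>
    dplyr::group_split()
  epochs <- list()
  rejected <- list()
  for (g in groups) {
    res <- tryCatch(
      as_accel_epoch(g[, need], sample_rate = sample_rate, duration = duration),
      error = function(e) e
    )
    key <- tibble::tibble(
      participant_id = g$participant_id[1], epoch_id = g$epoch_id[1]
    )
    if (inherits(res, "error")) {
      key$reason <- conditionMessage(res)
      rejected[[length(rejected) + 1L]] <- key
    } else {
      attr(res, "participant_id") <- key$participant_id
      attr(res, "epoch_id") <- key$epoch_id
      epochs[[length(epochs) + 1L]] <- res
    }
  }
  list(
    epochs = epochs,
    rejected = if (length(rejected)) dplyr::bind_rows(rejected) else
      tibble::tibble(participant_id = character(), epoch_id = integer(),
                     reason = character())
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, filter running epochs, summarize the week
#' into percentiles, build the three fall-risk models, and test the AUC
#' improvements Model 1 vs 2 and Model 2 vs 3 with the block-permutation
#' test. All stages derive their randomness from `params$seed` and the
#' `seed` argument, so reruns are identical.
#'
#' @param params A [cohort_params()] describing the synthetic cohort.
#' @param config A [gait_config()].
#' @param n_permutations Permutations for each model comparison.
#' @param seed Seed for the permutation draws.
#' @param out_dir Optional directory; when given, writes `summary.csv`
#'   (cohort table), `univariate.csv`, `models.json`, `roc_points.csv` and
#'   `comparisons.json` there.
#' @return A list with `cohort` (the `gait_cohort`), `models`
#'   (`risk_model_set`), `cmp_12` and `cmp_23` (`auc_comparison`s).
#' @export
run_pipeline <- function(params = cohort_params(), config = gait_config(),
                         n_permutations = config$permutation$n_permutations,
                         seed = 1L, out_dir = NULL) {
  cohort <- synth_cohort(params, config)
  models <- build_models(cohort$cohort, config)
  cmp_12 <- compare_models(cohort$cohort, "model1", "model2",
    n_permutations = n_permutations, seed = seed, config = config
  )
  cmp_23 <- compare_models(cohort$cohort, "model2", "model3",
    n_permutations = n_permutations, seed = seed + 1L, config = config
  )
  result <- list(cohort = cohort, models = models, cmp_12 = cmp_12, cmp_23 = cmp_23)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cohort$cohort, file.path(out_dir, "summary.csv"))
    readr::write_csv(models$scan, file.path(out_dir, "univariate.csv"))
    roc <- dplyr::bind_rows(lapply(models$models, function(m) {
      dplyr::mutate(roc_points(m$fitted, m$y), model_id = m$model_id)
    }))
    readr::write_csv(roc, file.path(out_dir, "roc_points.csv"))
    jsonlite::write_json(
      lapply(models$models, function(m) {
        list(
          model_id = m$model_id, terms = m$terms,
          coefficients = m$coefficients, auc = m$auc, hl_p = m$hl_p, n = m$n
        )
      }),
      file.path(out_dir, "models.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    jsonlite::write_json(
      list(model1_vs_model2 = glance(cmp_12), model2_vs_model3 = glance(cmp_23)),
      file.path(out_dir, "comparisons.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  result
}
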