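#' z-transform columns of a cohort table
#'
#' Centers and scales the requested columns to mean 0, SD 1, keeping the
#' scaling record for exact back-transformation. Constant (zero-SD) columns
#' cannot be standardized: they are left untouched and reported in
#' `flagged`, and downstream candidate screens exclude them.
#'
#' @param data A data frame.
#' @param cols Columns to transform (default: all numeric columns).
#' @return A list with `data` (transformed tibble), `center`, `scale`
#'   (named numeric vectors) and `flagged` (character).
#' @examples
#' z <- z_transform(tibble::tibble(x = 1:3))
#' z$data$x
#' back_transform(z)$x
#' @export
z_transform <- function(data, cols = NULL) {
  data <- tibble::as_tibble(data)
  cols <- cols %||% names(data)[vapply(data, is.numeric, logical(1))]
  center <- scale <- setNames(numeric(length(cols)), cols)
  flagged <- character(0)
  for (cl in cols) {
    x <- data[[cl]]
    mu <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      flagged <- c(flagged, cl)
      center[cl] <- mu
      scale[cl] <- 1
      next
    }
    center[cl] <- mu
    scale[cl] <- s
    data[[cl]] <- (x - mu) / s
  }
  list(data = data, center = center, scale = scale, flagged = flagged)
}

#' @rdname z_transform
#' @param record The list returned by [z_transform()].
#' @export
back_transform <- function(record) {
  data <- record$data
  for (cl in setdiff(names(record$center), record$flagged)) {
    data[[cl]] <- data[[cl]] * record$scale[cl] + record$center[cl]
  }
  data
}

wald_p <- function(est, se) 2 * pnorm(-abs(est / se))

# Matrix-level logistic fit (intercept added here). Returns the raw IRLS
# result plus Wald statistics.
fit_logit_matrix <- function(X, y, tol = 1e-8) {
  Xi <- if (is.null(X)) matrix(1, length(y), 1) else cbind(1, X)
  res <- logit_irls_cpp(Xi, as.numeric(y), tol = tol)
  res$p_values <- wald_p(res$coefficients, res$se)
  res
}

#' Maximum-likelihood logistic regression
#'
#' Newton-type fit (convergence tolerance 1e-8) with per-coefficient Wald
#' tests, used for both the univariate association scans and the stepwise
#' model building. Perfect or quasi-perfect separation is detected (diverging
#' coefficients or a singular information matrix) and reported via the
#' `separated`/`singular` flags and a warning, never returned silently.
#'
#' @param x Predictor data frame or matrix (no intercept column; one is
#'   added).
#' @param y Binary outcome vector (0/1).
#' @return A `gaitrisk_logit` object: `coefficients` tibble (term, estimate,
#'   std_error, statistic, p_value), `loglik`, `fitted`, `n`, `converged`,
#'   `separated`, `singular`.
#' @examples
#' fit <- fit_logistic(data.frame(x = rnorm(50)), rbinom(50, 1, 0.4))
#' tidy(fit)
#' @export
fit_logistic <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  terms <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  if (is.data.frame(x)) {
    terms <- names(x)
    x <- as.matrix(x)
  }
  stopifnot(all(y %in% c(0, 1)), length(y) == nrow(x))
  if (length(unique(y)) < 2) abort("outcome is degenerate (single class)")
  res <- fit_logit_matrix(x, y)
  if (res$separated || res$singular) {
    warn("possible separation or rank deficiency in logistic fit")
  }
  structure(
    list(
      coefficients = tibble::tibble(
        term = c("(Intercept)", terms),
        estimate = as.numeric(res$coefficients),
        std_error = as.numeric(res$se),
        statistic = as.numeric(res$coefficients / res$se),
        p_value = as.numeric(res$p_values)
      ),
      loglik = res$loglik,
      fitted = as.numeric(res$fitted),
      n = nrow(x),
      converged = res$converged,
      separated = res$separated,
      singular = res$singular
    ),
    class = "gaitrisk_logit"
  )
}

#' @method tidy gaitrisk_logit
#' @export
tidy.gaitrisk_logit <- function(x, ...) x$coefficients

#' @method glance gaitrisk_logit
#' @export
glance.gaitrisk_logit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n = x$n, converged = x$converged,
    separated = x$separated
  )
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC with ties counted as 1/2, equal to the
#' probability that a random faller receives a higher predicted risk than a
#' random non-faller. Invariant under strictly increasing transforms of
#' `p_hat`.
#'
#' @param p_hat Predicted risks (any monotone score).
#' @param y Binary outcomes.
#' @return AUC in `[0, 1]`; `NA` when only one class is present.
#' @export
roc_auc <- function(p_hat, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p_hat, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc
#' @return `roc_points()` returns a tibble with `threshold`, `fpr`, `tpr`
#'   tracing the empirical ROC curve.
#' @export
roc_points <- function(p_hat, y) {
  y <- as.integer(y)
  ord <- order(p_hat, decreasing = TRUE)
  ys <- y[ord]
  ps <- p_hat[ord]
  keep <- c(diff(ps) != 0, TRUE) # one point per distinct threshold
  tp <- cumsum(ys)[keep]
  fp <- cumsum(1 - ys)[keep]
  tibble::tibble(
    threshold = c(Inf, ps[keep]),
    fpr = c(0, fp / sum(y == 0)),
    tpr = c(0, tp / sum(y == 1))
  )
}

#' Hosmer-Lemeshow calibration test
#'
#' Groups observations into deciles of predicted risk and compares observed
#' and expected event counts with a chi-square statistic on `groups - 2`
#' degrees of freedom. Ties in the predicted risks that would leave a group
#' with fewer than 3 observations cause groups to be merged, with the
#' degrees of freedom adjusted and a warning raised.
#'
#' @param p_hat Predicted probabilities.
#' @param y Binary outcomes.
#' @param groups Number of risk groups (default deciles).
#' @return A list with `statistic`, `df`, `p_value`, and the per-group
#'   `table` (observed, expected, size).
#' @export
hosmer_lemeshow <- function(p_hat, y, groups = 10L) {
  n <- length(p_hat)
  stopifnot(n >= 2 * groups, length(y) == n)
  breaks <- unique(quantile(p_hat, seq(0, 1, length.out = groups + 1), type = 7))
  if (length(breaks) < 3) abort("predicted risks are too tied to group")
  g <- cut(p_hat, breaks, include.lowest = TRUE, labels = FALSE)
  tab <- tibble::tibble(
    n_g = as.numeric(tapply(y, g, length)),
    obs = as.numeric(tapply(y, g, sum)),
    pbar = as.numeric(tapply(p_hat, g, mean))
  )
  # merge undersized groups into their upper neighbour
  while (nrow(tab) > 2 && any(tab$n_g < 3)) {
    i <- which(tab$n_g < 3)[1]
    j <- if (i == nrow(tab)) i - 1L else i + 1L
    pooled_n <- tab$n_g[i] + tab$n_g[j]
    tab$pbar[j] <- (tab$pbar[i] * tab$n_g[i] + tab$pbar[j] * tab$n_g[j]) / pooled_n
    tab$obs[j] <- tab$obs[i] + tab$obs[j]
    tab$n_g[j] <- pooled_n
    tab <- tab[-i, , drop = FALSE]
  }
  if (nrow(tab) < groups || length(breaks) < groups + 1) {
    warn("risk groups merged due to ties; degrees of freedom adjusted")
  }
  expected <- tab$n_g * tab$pbar
  denom <- tab$n_g * tab$pbar * (1 - tab$pbar)
  terms <- ifelse(tab$obs == expected, 0, (tab$obs - expected)^2 / denom)
  statistic <- sum(terms)
  df <- max(1L, nrow(tab) - 2L)
  list(
    statistic = statistic, df = df,
    p_value = pchisq(statistic, df, lower.tail = FALSE),
    table = tibble::tibble(
      size = tab$n_g, observed = tab$obs, expected = expected
    )
  )
}

questionnaire_cols <- function() c("fall_history", "gds_score")

percentile_cols <- function(data) {
  grep("__p\\d+$", names(data), value = TRUE)
}

#' Univariate association scan
#'
#' Fits one single-predictor logistic regression of the fall outcome on each
#' z-transformed candidate: every gait characteristic at its 10th, 50th and
#' 90th percentile, plus the questionnaire and activity parameters. This
#' reproduces the shape of the study's univariate tables (log-odds per SD
#' with Wald P values).
#'
#' @param cohort Participant-level cohort table (see [synth_cohort()]).
#' @param outcome Name of the binary outcome column.
#' @param candidates Candidate columns; defaults to questionnaire +
#'   activities + all `<feature>__pXX` columns.
#' @return A tibble with `parameter`, `percentile` (10/50/90 or `NA` for
#'   questionnaire/activity parameters), `term` (column name), `B` (log-odds
#'   per SD), `p`, `n`. Constant columns are skipped with a note column.
#' @export
univariate_scan <- function(cohort, outcome = "faller", candidates = NULL) {
  candidates <- candidates %||% c(
    intersect(c(questionnaire_cols(), activity_names()), names(cohort)),
    percentile_cols(cohort)
  )
  y_all <- cohort[[outcome]]
  rows <- purrr::map(candidates, function(cl) {
    x <- cohort[[cl]]
    ok <- !is.na(x) & !is.na(y_all)
    x <- x[ok]
    y <- y_all[ok]
    s <- sd(x)
    is_pct <- grepl("__p\\d+$", cl)
    parameter <- if (is_pct) sub("__p\\d+$", "", cl) else cl
    pct <- if (is_pct) as.integer(sub("^.*__p", "", cl)) else NA_integer_
    if (is.na(s) || s == 0 || length(unique(y)) < 2) {
      return(tibble::tibble(
        parameter = parameter, percentile = pct, term = cl,
        B = NA_real_, p = NA_real_, n = length(x), note = "constant_or_degenerate"
      ))
    }
    fit <- fit_logit_matrix(matrix((x - mean(x)) / s, ncol = 1), y)
    tibble::tibble(
      parameter = parameter, percentile = pct, term = cl,
      B = res_coef(fit, 2), p = fit$p_values[2], n = length(x), note = ""
    )
  })
  dplyr::bind_rows(rows)
}

res_coef <- function(fit, i) as.numeric(fit$coefficients[i])

#' Choose the stronger percentile per characteristic
#'
#' A percentile value (10th, 50th or 90th) counts as having a stronger
#' association than the other two when its univariate regression P value is
#' the lowest of the three and below .05; otherwise the median is retained.
#' Characteristics with missing percentile results default to the median.
#'
#' @param scan Output of [univariate_scan()].
#' @param alpha Significance threshold for declaring a stronger association.
#' @return A tibble with `parameter`, `percentile` (the chosen one), `p`
#'   (its univariate P value) and `replaced` (`TRUE` when an extreme
#'   replaces the median).
#' @export
select_stronger_percentile <- function(scan, alpha = 0.05) {
  scan |>
    dplyr::filter(!is.na(.data$percentile)) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(function(df, key) {
      p <- df$p
      p[is.na(p)] <- Inf
      i <- which.min(p)
      if (is.finite(p[i]) && p[i] < alpha) {
        chosen <- df$percentile[i]
        pv <- df$p[i]
      } else {
        chosen <- 50L
        pv <- df$p[df$percentile == 50L][1] %||% NA_real_
      }
      tibble::tibble(percentile = chosen, p = pv, replaced = chosen != 50L)
    }) |>
    dplyr::ungroup()
}

# Core stepwise-forward selection on a pre-standardized candidate matrix.
# Z: n x p z-scored candidates; rho: p x p Spearman correlations; candidates
# are iterated in lexicographic name order so exact P ties break
# deterministically.
stepwise_core <- function(Z, y, rho, alpha = 0.05, rho_max = 0.7) {
  p <- ncol(Z)
  ord <- order(colnames(Z))
  selected <- integer(0)
  entry_p <- numeric(0)
  Xbase <- NULL
  best_fit <- NULL
  remaining <- ord
  repeat {
    best_p <- Inf
    best_j <- NA_integer_
    cand_fit <- NULL
    for (j in remaining) {
      if (length(selected) &&
          any(abs(rho[j, selected]) > rho_max, na.rm = TRUE)) next
      fit <- fit_logit_matrix(cbind(Xbase, Z[, j]), y)
      if (fit$singular || fit$separated) next
      pj <- fit$p_values[length(fit$p_values)]
      if (is.finite(pj) && pj < best_p) {
        best_p <- pj
        best_j <- j
        cand_fit <- fit
      }
    }
    if (is.na(best_j) || best_p >= alpha) break
    selected <- c(selected, best_j)
    entry_p <- c(entry_p, best_p)
    Xbase <- cbind(Xbase, Z[, best_j])
    best_fit <- cand_fit
    remaining <- setdiff(remaining, best_j)
  }
  if (is.null(best_fit)) best_fit <- fit_logit_matrix(NULL, y)
  list(selected = selected, entry_p = entry_p, fit = best_fit)
}

#' Stepwise forward logistic model building
#'
#' In every step the candidate whose added-coefficient Wald P value is lowest
#' and below `alpha` is selected, provided its absolute Spearman correlation
#' with every previously selected parameter does not exceed `rho_max`.
#' Selection stops when no candidate qualifies; if none ever qualifies an
#' intercept-only model is returned with a note. Candidates are standardized
#' (z-transformed) before fitting; the Spearman screen uses the original
#' columns (rank correlation is invariant to the transform). Exact ties in
#' the minimal P value break by lexicographic parameter order.
#'
#' @param data Cohort table.
#' @param candidates Character vector of candidate column names.
#' @param outcome Binary outcome column name.
#' @param alpha Entry threshold on the added-coefficient Wald P value.
#' @param rho_max Collinearity cap on |Spearman rho| between selected
#'   parameters.
#' @param model_id Optional identifier (1, 2 or 3) stored on the result.
#' @return A `risk_model` object; see [build_models()].
#' @export
stepwise_forward <- function(data, candidates, outcome = "faller",
                             alpha = 0.05, rho_max = 0.7, model_id = NA) {
  stopifnot(length(candidates) >= 1)
  keep <- complete.cases(data[, c(candidates, outcome)])
  df <- data[keep, , drop = FALSE]
  y <- df[[outcome]]
  X <- as.matrix(df[, candidates, drop = FALSE])
  sds <- apply(X, 2, sd)
  usable <- sds > 0
  Z <- scale(X[, usable, drop = FALSE])
  rho <- cor(apply(X[, usable, drop = FALSE], 2, rank), method = "pearson")
  res <- stepwise_core(Z, y, rho, alpha = alpha, rho_max = rho_max)
  new_risk_model(res, colnames(Z), y, model_id = model_id, n = nrow(df))
}

new_risk_model <- function(res, cand_names, y, model_id = NA, n = length(y)) {
  terms <- cand_names[res$selected]
  fit <- res$fit
  p_hat <- as.numeric(fit$fitted)
  auc <- roc_auc(p_hat, y)
  hl <- if (n >= 20 && length(unique(p_hat)) > 2) {
    tryCatch(suppressWarnings(hosmer_lemeshow(p_hat, y)),
             error = function(e) NULL)
  }
  structure(
    list(
      model_id = model_id,
      terms = terms,
      coefficients = tibble::tibble(
        term = c("(Intercept)", terms),
        estimate = as.numeric(fit$coefficients),
        std_error = as.numeric(fit$se),
        p_entry = c(NA_real_, res$entry_p),
        p_value = as.numeric(fit$p_values)
      ),
      auc = auc,
      hl_statistic = hl$statistic %||% NA_real_,
      hl_p = hl$p_value %||% NA_real_,
      loglik = fit$loglik,
      fitted = p_hat,
      y = y,
      n = n,
      note = if (length(terms) == 0) "no candidate qualified; intercept-only" else ""
    ),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  id <- if (is.na(x$model_id)) "" else paste0(" ", x$model_id)
  cat(sprintf(
    "<risk_model%s> %d parameters, AUC %.3f, Hosmer-Lemeshow p %.2f, n = %d\n",
    id, length(x$terms), x$auc, x$hl_p, x$n
  ))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) x$coefficients

#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, n_parameters = length(x$terms), auc = x$auc,
    hl_statistic = x$hl_statistic, hl_p = x$hl_p, logLik = x$loglik, n = x$n
  )
}

model_candidate_sets <- function(cohort, selection = NULL) {
  feats <- intersect(gait_feature_names(), unique(sub("__p\\d+$", "",
                                                      percentile_cols(cohort))))
  medians <- paste0(feats, "__p50")
  m1 <- intersect(questionnaire_cols(), names(cohort))
  m2 <- c(m1, intersect(activity_names(), names(cohort)), medians)
  m3 <- m2
  if (!is.null(selection)) {
    repl <- selection[selection$replaced & selection$parameter %in% feats, ]
    if (nrow(repl)) {
      from <- paste0(repl$parameter, "__p50")
      to <- paste0(repl$parameter, "__p", repl$percentile)
      m3[match(from, m3)] <- to
    }
  }
  list(model1 = m1, model2 = m2, model3 = m3)
}

#' Build the three fall-risk models
#'
#' Model 1 uses questionnaire data only (fall history and GDS score). Model 2
#' adds the seven activity amounts and the medians of all gait
#' characteristics. Model 3 starts from Model 2's candidates but replaces a
#' characteristic's median by its 10th or 90th percentile wherever the
#' univariate scan found the extreme's association stronger
#' ([select_stronger_percentile()]). Each model is built by
#' [stepwise_forward()] and carries its in-sample AUC (no cross-validation)
#' and Hosmer-Lemeshow calibration.
#'
#' @param cohort Participant-level cohort table with a binary `faller`
#'   outcome.
#' @param config A [gait_config()] (stepwise alpha and rho settings).
#' @param outcome Outcome column name.
#' @return A `risk_model_set`: list with `models` (the three `risk_model`s),
#'   `scan` (univariate results) and `selection` (percentile choices).
#' @examples
#' ch <- synth_cohort(cohort_params(n_participants = 60, seed = 3))
#' ms <- build_models(ch$cohort)
#' glance(ms)
#' @export
build_models <- function(cohort, config = gait_config(), outcome = "faller") {
  scan <- univariate_scan(cohort, outcome = outcome)
  selection <- select_stronger_percentile(scan, alpha = config$stepwise$alpha)
  sets <- model_candidate_sets(cohort, selection)
  models <- purrr::imap(sets, function(cands, nm) {
    stepwise_forward(cohort, cands,
      outcome = outcome,
      alpha = config$stepwise$alpha, rho_max = config$stepwise$rho_max,
      model_id = as.integer(sub("model", "", nm))
    )
  })
  structure(
    list(models = models, scan = scan, selection = selection),
    class = "risk_model_set"
  )
}

#' @method glance risk_model_set
#' @export
glance.risk_model_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, glance))
}

#' @method tidy risk_model_set
#' @export
tidy.risk_model_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, function(m) {
    dplyr::mutate(tidy(m), model_id = m$model_id, .before = 1)
  }))
}

#' @export
print.risk_model_set <- function(x, ...) {
  cat("<risk_model_set>\n")
  print(glance(x))
  invisible(x)
}

#' ROC curves of a fitted model set
#'
#' @param object A `risk_model` or `risk_model_set`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve(s) with AUC in the legend.
#' @method autoplot risk_model_set
#' @export
autoplot.risk_model_set <- function(object, ...) {
  pts <- dplyr::bind_rows(lapply(object$models, function(m) {
    dplyr::mutate(
      roc_points(m$fitted, m$y),
      model = sprintf("Model %s (AUC %.3f)", m$model_id, m$auc)
    )
  }))
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot risk_model
#' @export
autoplot.risk_model <- function(object, ...) {
  pts <- roc_points(object$fitted, object$y)
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}
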