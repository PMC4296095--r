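test_that("z_transform standardizes, flags constants, and inverts exactly", {
  z <- z_transform(tibble::tibble(x = c(1, 2, 3), k = c(5, 5, 5)))
  expect_equal(mean(z$data$x), 0)
  expect_equal(sd(z$data$x), 1)
  expect_equal(z$flagged, "k")
  expect_equal(back_transform(z)$x, c(1, 2, 3))
})

test_that("intercept-only fit reproduces the marginal log-odds of 70/202 fallers", {
  y <- c(rep(1, 70), rep(0, 132))
  fit0 <- gaitrisk:::fit_logit_matrix(NULL, y)
  expect_equal(as.numeric(fit0$coefficients), log(70 / 132), tolerance = 1e-8)
})

test_that("logistic fits agree with glm and with the grid-search oracle", {
  withr::with_seed(31, {
    x <- rnorm(120)
    y <- rbinom(120, 1, plogis(-0.4 + 0.9 * x))
  })
  fit <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), y)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$std_error,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)

  # tiny hand datasets against brute-force likelihood maximization
  hands <- list(
    list(x = c(-1.2, -0.5, 0.1, 0.4, 1.1, 1.7), y = c(0, 1, 0, 1, 1, 1)),
    list(x = c(0.2, 0.5, 0.9, 1.4, 2.2, 3.0, 0.1, 1.8),
         y = c(0, 0, 1, 0, 1, 1, 0, 1)),
    list(x = c(-2, -1, 0, 1, 2, 0.5), y = c(0, 1, 0, 1, 0, 1))
  )
  for (h in hands) {
    fit <- fit_logistic(matrix(h$x, dimnames = list(NULL, "x")), h$y)
    oracle <- logit_grid_oracle(h$x, h$y)
    expect_equal(fit$coefficients$estimate, unname(oracle), tolerance = 1e-4)
  }
})

test_that("perfect separation is detected and reported, not silently returned", {
  x <- c(-3, -2, -1, 1, 2, 3, -2.5, 2.5, -1.5, 1.5)
  y <- as.numeric(x > 0)
  expect_warning(fit <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), y),
                 "separation")
  expect_true(fit$separated)
})

test_that("AUC: perfect separation, null behavior, exact oracle equality", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  withr::with_seed(32, {
    p <- runif(2000)
    y <- rbinom(2000, 1, 0.4)
  })
  expect_lt(abs(roc_auc(p, y) - 0.5), 0.05)

  withr::with_seed(33, {
    for (i in 1:10) {
      n <- sample(8:25, 1)
      ph <- sample(seq(0, 1, 0.1), n, replace = TRUE) # forces ties
      yy <- rbinom(n, 1, 0.5)
      if (length(unique(yy)) < 2) yy[1:2] <- c(0, 1)
      expect_identical(roc_auc(ph, yy), auc_brute(ph, yy))
    }
  })
})

test_that("roc_points traces a curve from (0,0) to (1,1) consistent with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(34, {
    p <- runif(60)
    y <- rbinom(60, 1, p)
  })
  pts <- roc_points(p, y)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  ref <- pROC::roc(y, p, quiet = TRUE, direction = "<")
  expect_equal(roc_auc(p, y), as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("Hosmer-Lemeshow: zero statistic under exact calibration; hand formula", {
  # two risk strata whose observed frequencies equal their predictions
  p_hat <- rep(c(0.2, 0.8), each = 50)
  y <- c(rep(1, 10), rep(0, 40), rep(1, 40), rep(0, 10))
  suppressWarnings(hl <- hosmer_lemeshow(p_hat, y))
  expect_equal(hl$statistic, 0)
  expect_equal(hl$p_value, 1)

  # four-group construction vs the definitional sum
  withr::with_seed(35, {
    p4 <- rep(c(0.1, 0.3, 0.6, 0.9), each = 25)
    y4 <- rbinom(100, 1, p4)
  })
  suppressWarnings(hl4 <- hosmer_lemeshow(p4, y4, groups = 4))
  byhand <- sum((hl4$table$observed - hl4$table$expected)^2 /
                  (hl4$table$expected * (1 - hl4$table$expected / hl4$table$size)))
  expect_equal(hl4$statistic, byhand, tolerance = 1e-10)
})

test_that("Hosmer-Lemeshow rejects a well-specified model at ~nominal rate", {
  withr::with_seed(36, {
    rejections <- vapply(1:400, function(i) {
      x <- rnorm(200)
      y <- rbinom(200, 1, plogis(-0.5 + x))
      fit <- gaitrisk:::fit_logit_matrix(matrix(x), y)
      hl <- hosmer_lemeshow(as.numeric(fit$fitted), y)
      hl$p_value < 0.05
    }, logical(1))
  })
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.10)
})

test_that("the stronger-percentile rule follows lowest-p-below-.05, else median", {
  scan <- tibble::tibble(
    parameter = rep(c("frequency_variability_ap", "harmonic_ratio_vt", "flat"), each = 3),
    percentile = rep(c(10L, 50L, 90L), 3),
    term = paste0(parameter, "__p", percentile),
    B = 0,
    p = c(.03, .07, .61, .83, .009, .003, .30, .20, .40),
    n = 202
  )
  sel <- select_stronger_percentile(scan)
  expect_equal(sel$percentile[sel$parameter == "frequency_variability_ap"], 10L)
  expect_equal(sel$percentile[sel$parameter == "harmonic_ratio_vt"], 90L)
  expect_equal(sel$percentile[sel$parameter == "flat"], 50L)
  expect_false(sel$replaced[sel$parameter == "flat"])
})

test_that("duplicated predictors give identical scan rows; rho screen keeps one", {
  ch <- synth_cohort(cohort_params(
    n_participants = 120, epochs_per_participant = 10,
    outcome_coefficients = c(sample_entropy_vt__p50 = 0.9), seed = 61
  ))
  cohort <- ch$cohort
  cohort$copy_a <- cohort$sample_entropy_vt__p50
  cohort$copy_b <- cohort$sample_entropy_vt__p50
  sc <- univariate_scan(cohort, candidates = c("copy_a", "copy_b"))
  expect_equal(sc$B[1], sc$B[2])
  expect_equal(sc$p[1], sc$p[2])

  m <- stepwise_forward(cohort, c("copy_a", "copy_b"), outcome = "faller")
  expect_equal(length(m$terms), 1L)
})

test_that("stepwise selects an informative candidate and respects the rho cap", {
  ch <- synth_cohort(cohort_params(
    n_participants = 300, epochs_per_participant = 10,
    outcome_coefficients = c(sample_entropy_vt__p50 = 0.8), seed = 62
  ))
  m2 <- build_models(ch$cohort)$models$model2
  expect_true("sample_entropy_vt__p50" %in% m2$terms)

  # post-hoc: every selected pair satisfies |spearman rho| <= 0.7
  if (length(m2$terms) > 1) {
    rho <- cor(ch$cohort[, m2$terms], method = "spearman")
    expect_true(all(abs(rho[upper.tri(rho)]) <= 0.7))
  }
})

test_that("no qualifying candidate yields an annotated intercept-only model", {
  withr::with_seed(63, {
    df <- tibble::tibble(
      a = rnorm(80), b = rnorm(80), faller = rbinom(80, 1, 0.4)
    )
  })
  m <- stepwise_forward(df, c("a", "b"), alpha = 1e-9)
  expect_length(m$terms, 0)
  expect_match(m$note, "intercept-only")
  expect_equal(m$auc, 0.5)
})

test_that("alpha = 1 keeps selecting until no admissible candidate remains", {
  withr::with_seed(64, {
    df <- tibble::tibble(
      a = rnorm(60), b = rnorm(60), c = rnorm(60),
      faller = rbinom(60, 1, 0.5)
    )
  })
  m <- stepwise_forward(df, c("a", "b", "c"), alpha = 1)
  expect_equal(sort(m$terms), c("a", "b", "c"))
})

test_that("model building is deterministic given cohort and config", {
  ch <- synth_cohort(cohort_params(n_participants = 80, seed = 65))
  m1 <- build_models(ch$cohort)
  m2 <- build_models(ch$cohort)
  expect_identical(glance(m1), glance(m2))
  expect_identical(tidy(m1), tidy(m2))
})

test_that("tidy and glance expose the model-set results", {
  ch <- synth_cohort(cohort_params(n_participants = 80, seed = 66))
  ms <- build_models(ch$cohort)
  g <- glance(ms)
  expect_equal(g$model_id, 1:3)
  expect_true(all(g$auc >= 0 & g$auc <= 1, na.rm = TRUE))
  td <- tidy(ms)
  expect_true(all(c("model_id", "term", "estimate", "p_value") %in% names(td)))
  p <- autoplot(ms)
  expect_s3_class(p, "ggplot")
})
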