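make_test_cohort <- function(seed = 71, n = 80, coefs = NULL) {
  synth_cohort(cohort_params(
    n_participants = n, epochs_per_participant = 10,
    outcome_coefficients = coefs %||% default_coefs(), seed = seed
  ))$cohort
}

default_coefs <- function() c(fall_history = 0.5, gds_score = 0.4)

test_that("sensor-block permutation preserves the block and fixes the rest", {
  cohort <- make_test_cohort()
  permuted <- permute_sensor_block(cohort, seed = 5)
  sensor <- gaitrisk:::sensor_block_cols(cohort)

  # identity permutation leaves the cohort unchanged
  same <- permute_sensor_block(cohort, perm = seq_len(nrow(cohort)))
  expect_equal(tibble::as_tibble(same), cohort, ignore_attr = TRUE)

  # column-wise distributions and within-block correlations survive
  for (cl in sensor[c(1, 5, 10, 40)]) {
    expect_equal(sort(permuted[[cl]]), sort(cohort[[cl]]))
  }
  sub <- sensor[c(1, 3, 8, 20)]
  expect_equal(
    cor(as.matrix(permuted[, sub]), method = "spearman"),
    cor(as.matrix(cohort[, sub]), method = "spearman"),
    tolerance = 1e-12
  )

  # questionnaire and outcome are untouched, bitwise
  expect_identical(permuted$faller, cohort$faller)
  expect_identical(permuted$fall_history, cohort$fall_history)
  expect_identical(permuted$gds_score, cohort$gds_score)
})

test_that("comparing a model specification with itself gives delta 0 and p 0", {
  cohort <- make_test_cohort(seed = 72)
  cmp <- compare_models(cohort, "model2", "model2",
                        n_permutations = 29, seed = 2)
  expect_equal(cmp$observed_delta_auc, 0)
  expect_true(all(cmp$permutations$delta == 0))
  expect_equal(cmp$p, 0)
})

test_that("the comparison is fully reproducible from (cohort, spec, seed)", {
  cohort <- make_test_cohort(seed = 73)
  a <- compare_models(cohort, "model1", "model2", n_permutations = 39, seed = 9)
  b <- compare_models(cohort, "model1", "model2", n_permutations = 39, seed = 9)
  expect_identical(glance(a), glance(b))
  expect_identical(a$permutations, b$permutations)
  c2 <- compare_models(cohort, "model1", "model2", n_permutations = 39, seed = 10)
  expect_false(identical(a$permutations$delta, c2$permutations$delta))
})

test_that("a strong sensor signal is declared a significant improvement", {
  cohort <- make_test_cohort(
    seed = 74, n = 300,
    coefs = c(sample_entropy_vt__p50 = 1.0)
  )
  cmp <- compare_models(cohort, "model1", "model2",
                        n_permutations = 99, seed = 4)
  expect_gt(cmp$observed_delta_auc, 0.05)
  expect_lt(cmp$p, 0.05)
})

test_that("the small-sample-corrected estimator is (k+1)/(n+1)", {
  cohort <- make_test_cohort(seed = 75)
  cmp0 <- compare_models(cohort, "model1", "model2",
                         n_permutations = 19, seed = 8)
  cmp1 <- compare_models(cohort, "model1", "model2",
                         n_permutations = 19, seed = 8,
                         small_sample_correction = TRUE)
  k <- sum(cmp0$permutations$delta > cmp0$observed_delta_auc)
  expect_equal(cmp0$p, k / 19)
  expect_equal(cmp1$p, (k + 1) / 20)
})

test_that("permuted baseline AUCs are reported for the conservativeness check", {
  cohort <- make_test_cohort(
    seed = 76, n = 150,
    coefs = c(fall_history = 0.5, sample_entropy_vt__p50 = 0.8)
  )
  cmp <- compare_models(cohort, "model2", "model3",
                        n_permutations = 29, seed = 6)
  g <- glance(cmp)
  expect_true(is.finite(g$mean_permuted_auc_a))
  # under permutation the sensor signal is destroyed: baseline typically drops
  expect_lt(g$mean_permuted_auc_a, cmp$observed_auc_a)
})
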