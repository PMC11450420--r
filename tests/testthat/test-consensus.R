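test_that("perfectly separable point-masses give a 0/1 consensus and exact recovery", {
  x <- rbind(matrix(0L, 30, 13), matrix(1L, 30, 13))
  imps <- as_imputation_set(x)
  set.seed(1)
  cr <- consensus_kmeans(imps, k = 2, R = 10, p = 0.8, seed = 3)
  truth <- rep(1:2, each = 30)
  within <- outer(truth, truth, `==`)
  expect_true(all(cr$consensus[within] == 1))
  expect_true(all(cr$consensus[!within] == 0))
  expect_equal(adjusted_rand_index(cr$labels, truth), 1)
})

test_that("contract violations are rejected up front", {
  imps <- as_imputation_set(matrix(rbinom(600, 1, 0.5), 60, 10))
  expect_error(consensus_kmeans(imps, k = 1, R = 10, p = 0.8), "2 <= k")
  expect_error(consensus_kmeans(imps, k = 20, R = 10, p = 0.8), "2 <= k")
  expect_error(consensus_kmeans(imps, k = 2, R = 10, p = 0.3), "\\[0.5, 1\\]")
  expect_error(consensus_kmeans(imps, k = 2, R = 5, p = 0.8), "at least 10")
})

test_that("consensus matrices are symmetric, unit-diagonal and in [0, 1]", {
  cfg <- separable_generator(n = 300, k = 3, seed = 51)
  co <- generate_cohort(cfg)
  imps <- as_imputation_set(derive_indicators(co)$values * 1L)
  cr <- consensus_kmeans(imps, k = 3, R = 15, p = 0.8, seed = 7)
  expect_true(isSymmetric(cr$consensus))
  expect_true(all(diag(cr$consensus) == 1))
  expect_true(all(cr$consensus >= 0 & cr$consensus <= 1))
  expect_true(all(sort(unique(cr$labels)) == 1:3))
})

test_that("labels are severity-ordered by mean indicator burden", {
  cfg <- separable_generator(n = 400, k = 4, seed = 53)
  co <- generate_cohort(cfg)
  imps <- as_imputation_set(derive_indicators(co)$values * 1L)
  cr <- consensus_kmeans(imps, k = 4, R = 15, p = 0.8, seed = 9)
  expect_true(all(diff(cr$cluster_burden) > 0))
  burden <- rowSums(imps$completed[[1]])
  means <- tapply(burden, cr$labels, mean)
  expect_true(all(diff(means) > 0))
})

test_that("duplicating every episode leaves the partition of patterns unchanged", {
  cfg <- separable_generator(n = 250, k = 3, seed = 57)
  co <- generate_cohort(cfg)
  x <- derive_indicators(co)$values * 1L
  cr1 <- consensus_kmeans(as_imputation_set(x), k = 3, R = 15, p = 0.8,
                          seed = 11)
  cr2 <- consensus_kmeans(as_imputation_set(rbind(x, x)), k = 3, R = 15,
                          p = 0.8, seed = 11)
  expect_equal(adjusted_rand_index(cr1$labels, cr2$labels[seq_len(nrow(x))]), 1)
  expect_equal(adjusted_rand_index(cr2$labels[seq_len(nrow(x))],
                                   cr2$labels[nrow(x) + seq_len(nrow(x))]), 1)
})

test_that("adjusted Rand index matches known values and the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
  set.seed(61)
  for (i in 1:10) {
    a <- sample(1:3, 25, replace = TRUE)
    b <- sample(1:4, 25, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), pair_counting_ari(a, b),
                 tolerance = 1e-12)
  }
})

test_that("a homogeneous cohort is flagged as having no stable structure", {
  set.seed(63)
  x <- matrix(rbinom(700 * 13, 1, 0.5), 700, 13)
  sk <- select_k(as_imputation_set(x), k_range = 2:4, R = 12, p = 0.8,
                 seed = 13)
  expect_true(sk$no_structure)
  expect_true(all(sk$diagnostics$pac > 0.4))
})

test_that("consensus artefacts serialise deterministically", {
  cfg <- separable_generator(n = 200, k = 2, seed = 67)
  co <- generate_cohort(cfg)
  imps <- as_imputation_set(derive_indicators(co)$values * 1L)
  cr <- consensus_kmeans(imps, k = 2, R = 12, p = 0.8, seed = 15)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_consensus_result(cr, d1)
  write_consensus_result(cr, d2)
  expect_identical(
    unname(tools::md5sum(file.path(d1, "cluster_labels.csv"))),
    unname(tools::md5sum(file.path(d2, "cluster_labels.csv")))
  )
  expect_identical(
    unname(tools::md5sum(file.path(d1, "consensus_matrix.csv"))),
    unname(tools::md5sum(file.path(d2, "consensus_matrix.csv")))
  )
})
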