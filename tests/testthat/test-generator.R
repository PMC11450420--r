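test_that("cluster shares converge to the configured mixture without demographic tilting", {
  n <- 20000
  cfg <- generator_config(n_episodes = n, demographic_effects = list(),
                          all_missing_fraction = 0, seed = 11)
  ep <- sample_clusters(cfg)
  shares <- tabulate(ep$.true_cluster, 4) / n
  bound <- 3 * sqrt(cfg$cluster_proportions * (1 - cfg$cluster_proportions) / n)
  expect_true(all(abs(shares - cfg$cluster_proportions) < bound))
})

test_that("within-cluster indicator prevalence matches the planted profile", {
  cfg <- small_generator(n = 12000, seed = 3)
  co <- generate_cohort(cfg)
  ind <- derive_indicators(co)
  for (cl in 1:4) {
    rows <- co$episodes$.true_cluster == cl
    n_c <- sum(rows)
    prev <- colMeans(ind$values[rows, , drop = FALSE] == 1L)
    p <- cfg$indicator_profiles[cl, ]
    bound <- 3 * sqrt(pmax(p * (1 - p), 0.002) / n_c)
    expect_true(all(abs(prev - p) < bound),
                info = sprintf("cluster %d", cl))
  }
})

test_that("generation is a pure function of the config, including the seed", {
  cfg <- small_generator(n = 400, seed = 21, missing_rate_item = 0.1,
                         all_missing_fraction = 0.1)
  a <- apply_missingness(generate_cohort(cfg), cfg)
  b <- apply_missingness(generate_cohort(cfg), cfg)
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$visits, b$visits)
  cfg2 <- small_generator(n = 400, seed = 22)
  c2 <- generate_cohort(cfg2)
  expect_false(identical(a$visits, c2$visits))
})

test_that("degenerate mixture puts every episode in one cluster", {
  cfg <- generator_config(n_episodes = 200, cluster_proportions = c(1, 0, 0, 0),
                          demographic_effects = list(),
                          all_missing_fraction = 0, seed = 1)
  ep <- sample_clusters(cfg)
  expect_true(all(ep$.true_cluster == 1L))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(100, cluster_proportions = c(0.5, 0.6)),
               "sum to 1")
  expect_error(generator_config(2), "at least the number of clusters")
  expect_error(generator_config(100, all_missing_fraction = 1),
               "\\[0, 1\\)")
  expect_error(generator_config(100, visit_rate_by_cluster = c(1, 2)),
               "positive means")
})

test_that("all-missing stratum hits its configured share", {
  n <- 100000
  cfg <- small_generator(n = n, seed = 5, all_missing_fraction = 0.141)
  co <- apply_missingness(generate_cohort(cfg), cfg)
  n_all <- sum(co$episodes$.all_missing)
  bound <- 3 * sqrt(n * 0.141 * (1 - 0.141))
  expect_lt(abs(n_all - n * 0.141), bound)
  # all-missing episodes really carry no indicator information
  ind <- derive_indicators(co)
  expect_true(all(rowSums(ind$observed_mask[co$episodes$.all_missing, ]) == 0))
})

test_that("zero missingness is a no-op", {
  cfg <- small_generator(n = 300, seed = 9)
  co <- generate_cohort(cfg)
  co2 <- apply_missingness(co, cfg)
  expect_identical(co$visits, co2$visits)
})

test_that("MAR missingness reproduces the configured odds ratio", {
  n <- 50000
  cfg <- generator_config(
    n_episodes = n, seed = 13, missing_rate_item = 0.1,
    all_missing_fraction = 0, missing_mechanism = "MAR",
    mar_covariate = "gender", mar_level = "male", mar_odds = 2
  )
  co <- apply_missingness(generate_cohort(cfg), cfg)
  ind <- derive_indicators(co)
  # k10 source missing <=> distress mask false
  miss <- !ind$observed_mask[, "distress"]
  male <- co$episodes$gender == "male"
  tab <- table(male, miss)
  or <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
    (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  se_log_or <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or) - log(2)), 3 * se_log_or)
})

test_that("separable profiles meet the pairwise mean-gap guarantee", {
  for (k in 2:4) {
    p <- separable_indicator_profiles(k)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        expect_gte(mean(abs(p[i, ] - p[j, ])), 0.5)
      }
    }
    expect_true(all(diff(rowSums(p)) > 0)) # strictly increasing burden
  }
  expect_error(separable_indicator_profiles(5), "2\\.\\.4")
})

test_that("cohorts round-trip through the delimited-text format", {
  cfg <- small_generator(n = 150, seed = 31, missing_rate_item = 0.2)
  co <- apply_missingness(generate_cohort(cfg), cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$episodes), nrow(co$episodes))
  expect_equal(back$visits$k10_total, co$visits$k10_total)
  expect_equal(back$visits$stage, co$visits$stage)
  expect_identical(
    derive_indicators(back)$values,
    derive_indicators(co)$values
  )
})
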