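test_that("the default indicator set has 13 uniquely named definitions", {
  defs <- default_indicator_set()
  expect_length(defs, 13)
  expect_identical(names(defs), complexity_indicator_names())
  expect_false(anyDuplicated(names(defs)) > 0)
})

test_that("distress and functioning thresholds sit exactly at the cut-points", {
  co <- toy_cohort(tibble::tibble(
    episode_id = c("a", "b", "c", "d"),
    k10_total = c(31L, 30L, NA, NA),
    sofas = c(NA, NA, 60L, 61L)
  ))
  ind <- derive_indicators(co)
  expect_equal(ind$values[, "distress"], c(1L, 0L, NA, NA))
  expect_equal(ind$values[, "low_functioning"], c(NA, NA, 1L, 0L))
})

test_that("any-visit aggregation fires on a single qualifying visit", {
  co <- toy_cohort(tibble::tibble(
    episode_id = c("a", "a", "a"),
    k10_total = c(25L, 35L, 28L)
  ))
  ind <- derive_indicators(co)
  expect_equal(ind$values[1, "distress"], 1L, ignore_attr = TRUE)
})

test_that("never-measured sources yield missing, measured-but-absent yields zero", {
  co <- toy_cohort(tibble::tibble(
    episode_id = "a", sofas = 55L, k10_total = 12L
  ))
  ind <- derive_indicators(co)
  expect_equal(ind$values[1, "low_functioning"], 1L, ignore_attr = TRUE)
  expect_equal(ind$values[1, "distress"], 0L, ignore_attr = TRUE)
  expect_equal(sum(ind$observed_mask[1, ]), 2)
})

test_that("unknown source fields raise a schema error naming the field", {
  co <- toy_cohort(tibble::tibble(episode_id = "a", k10_total = 12L))
  defs <- default_indicator_set()
  defs[[1]]$source_fields <- "k10_banana"
  expect_error(derive_indicators(co, defs), "k10_banana")
})

test_that("derive_indicators round-trips planted states under zero missingness", {
  cfg <- small_generator(n = 800, seed = 17)
  co <- generate_cohort(cfg)
  ind <- derive_indicators(co)
  expect_true(all(ind$observed_mask))
  expect_identical(unname(ind$values == 1L), unname(co$planted))
})

test_that("adding a visit is monotone: indicators never flip 1 -> 0", {
  cfg <- small_generator(n = 200, seed = 23)
  co <- generate_cohort(cfg)
  ind_full <- derive_indicators(co)
  # drop each episode's last visit (episodes with >= 2 visits)
  keep <- co$visits$visit_number <
    stats::ave(co$visits$visit_number, co$visits$episode_id, FUN = max) |
    stats::ave(co$visits$visit_number, co$visits$episode_id, FUN = max) == 1
  co_trunc <- co
  co_trunc$visits <- co$visits[keep, ]
  ind_trunc <- derive_indicators(co_trunc)
  was_one <- !is.na(ind_trunc$values) & ind_trunc$values == 1L
  expect_true(all(ind_full$values[was_one] == 1L))
})

test_that("exclusion filter removes exactly the all-missing rows and conserves counts", {
  vals <- rbind(c(1, 0, 1), c(NA, NA, NA), c(0, 0, NA), c(NA, NA, NA),
                c(1, NA, NA))
  m <- indicator_matrix(vals, episode_ids = 1:5)
  fl <- exclusion_filter(m)
  expect_equal(fl$matrix$episode_ids, c(1L, 3L, 5L))
  expect_equal(fl$report$n_excluded, 2)
  expect_equal(fl$report$n_total,
               fl$report$n_excluded + fl$report$n_retained)
  # idempotent
  fl2 <- exclusion_filter(fl$matrix)
  expect_equal(fl2$report$n_excluded, 0)
  expect_identical(fl2$matrix$values, fl$matrix$values)
  # fully missing input halts
  all_na <- indicator_matrix(matrix(NA_integer_, 3, 3))
  expect_error(exclusion_filter(all_na), "no episodes retained")
})

test_that("prevalence uses observed-only denominators and flags empty groups", {
  m <- indicator_matrix(rbind(c(1), c(0), c(NA), c(NA)),
                        episode_ids = 1:4)
  pv <- prevalence_by_group(m, grouping = c("g1", "g1", "g1", "g2"))
  expect_equal(pv$prevalence[pv$group == "g1"], 0.5)
  expect_equal(pv$n_observed[pv$group == "g1"], 2L)
  expect_true(is.na(pv$prevalence[pv$group == "g2"]))

  m2 <- indicator_matrix(matrix(c(1, 1, 0, 1), 4, 1))
  pv2 <- prevalence_by_group(m2)
  expect_equal(pv2$prevalence, 0.75)
})

test_that("overall distress prevalence on the default cohort exceeds one half", {
  cfg <- small_generator(n = 6000, seed = 29)
  ind <- derive_indicators(generate_cohort(cfg))
  pv <- prevalence_by_group(ind)
  expect_gt(pv$prevalence[pv$indicator == "distress"], 0.50)
})

test_that("indicator matrices round-trip through the paired-column format", {
  cfg <- small_generator(n = 120, seed = 37, missing_rate_item = 0.3)
  co <- apply_missingness(generate_cohort(cfg), cfg)
  m <- derive_indicators(co)
  path <- withr::local_tempfile(fileext = ".csv")
  write_indicator_matrix(m, path)
  back <- read_indicator_matrix(path)
  expect_identical(back$values, m$values)
  expect_identical(back$observed_mask, m$observed_mask)
  expect_equal(back$episode_ids, m$episode_ids)
})
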