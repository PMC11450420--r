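test_that("pooling identical completed datasets reproduces the single-dataset matrix", {
  set.seed(81)
  x <- matrix(rbinom(500 * 5, 1, 0.4), 500, 5)
  colnames(x) <- paste0("v", 1:5)
  net1 <- pooled_tetrachoric(as_imputation_set(x), layout = FALSE)
  net2 <- pooled_tetrachoric(as_imputation_set(list(x, x)), layout = FALSE)
  expect_equal(net2$rho, net1$rho, tolerance = 1e-10)
  expect_equal(net2$pooled_from, 2)
})

test_that("a planted latent correlation of 0.6 is recovered within 0.05", {
  set.seed(83)
  gen <- function() {
    n <- 5000
    z1 <- rnorm(n)
    z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
    x <- cbind(a = as.integer(z1 > 0), b = as.integer(z2 > 0))
    for (j in 1:4) x <- cbind(x, rbinom(n, 1, 0.4))
    colnames(x)[3:6] <- paste0("noise", 1:4)
    x
  }
  net <- pooled_tetrachoric(as_imputation_set(list(gen(), gen())),
                            layout = FALSE)
  expect_lt(abs(net$rho["a", "b"] - 0.6), 0.05)
  expect_lt(max(abs(net$rho["a", paste0("noise", 1:4)])), 0.1)
})

test_that("edge list covers all unordered pairs and mirrors the matrix", {
  set.seed(85)
  x <- matrix(rbinom(400 * 4, 1, 0.5), 400, 4)
  net <- pooled_tetrachoric(as_imputation_set(x), layout = FALSE)
  expect_equal(nrow(net$edge_list), choose(4, 2))
  expect_equal(net$edge_list$rho[1], net$rho[1, 2])
})

test_that("three uncorrelated items lay out as an equilateral triangle", {
  rho <- diag(3)
  dimnames(rho) <- list(letters[1:3], letters[1:3])
  xy <- mds_layout(rho)
  d <- as.matrix(dist(xy))
  off <- d[upper.tri(d)]
  expect_lt(max(off) - min(off), 1e-9)
  expect_equal(colMeans(xy), c(dim1 = 0, dim2 = 0), tolerance = 1e-12)
})

test_that("perfectly correlated items are coincident in the layout", {
  rho <- matrix(c(1, 1, 0.3,
                  1, 1, 0.3,
                  0.3, 0.3, 1), 3, 3)
  dimnames(rho) <- list(letters[1:3], letters[1:3])
  xy <- suppressWarnings(mds_layout(rho))
  expect_lt(max(abs(xy[1, ] - xy[2, ])), 1e-6)
})

test_that("orientation is fixed: same matrix, same layout", {
  set.seed(87)
  x <- matrix(rbinom(800 * 6, 1, 0.5), 800, 6)
  net <- pooled_tetrachoric(as_imputation_set(x))
  net2 <- pooled_tetrachoric(as_imputation_set(x))
  expect_identical(net$layout, net2$layout)
  expect_gte(net$layout[1, 1], 0)
})

test_that("the default cohort's pooled network embeds with low stress and the expected blocks", {
  cfg <- small_generator(n = 3000, seed = 91, missing_rate_item = 0.1)
  co <- apply_missingness(generate_cohort(cfg), cfg)
  fl <- exclusion_filter(derive_indicators(co))
  imp <- impute_indicators(fl$matrix, m_count = 2, seed = 92, sweeps = 3)
  net <- pooled_tetrachoric(imp)
  # distress couples to quality of life; housing to NEET and benefits
  expect_gt(net$rho["distress", "low_quality_of_life"], 0.5)
  expect_gt(net$rho["housing_issues", "neet"], 0.5)
  expect_gt(net$rho["housing_issues", "government_benefits"], 0.5)
  # the 2-d layout keeps correlated blocks adjacent and improves on 1-d
  d <- sqrt(2 * (1 - net$rho))
  dl <- as.matrix(dist(net$layout))
  med <- stats::median(dl[upper.tri(dl)])
  expect_lt(dl["distress", "low_quality_of_life"], med)
  expect_lt(dl["housing_issues", "neet"], med)
  expect_lt(dl["neet", "government_benefits"], med)
  xy1 <- stats::cmdscale(stats::as.dist(d), k = 1)
  expect_lt(layout_stress(d, cbind(net$layout)),
            layout_stress(d, cbind(xy1, 0)))
  # artefact round trip
  dir <- withr::local_tempdir()
  paths <- write_tetra_network(net, dir)
  expect_true(all(file.exists(paths)))
  edges <- data.table::fread(paths["edges"])
  expect_equal(nrow(edges), choose(13, 2))
})
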