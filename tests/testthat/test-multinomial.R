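test_that("a 2x2 table reproduces the closed-form log odds ratio", {
  x <- cbind(1, c(rep(0, 30), rep(1, 70)))
  y <- c(rep(1, 10), rep(2, 20), rep(1, 40), rep(2, 30))
  fit <- fit_multinomial(x, y)
  expect_equal(fit$coef[2, 1], log((30 * 10) / (20 * 40)), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("coefficients match a brute-force likelihood maximiser on a toy problem", {
  set.seed(95)
  n <- 200
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  eta2 <- 0.5 + 0.8 * x[, 2] - 0.4 * x[, 3]
  eta3 <- -0.3 + 0.2 * x[, 2] + 0.9 * x[, 3]
  pr <- exp(cbind(0, eta2, eta3))
  pr <- pr / rowSums(pr)
  y <- vapply(seq_len(n), function(i) sample(1:3, 1, prob = pr[i, ]), 0L)
  fit <- fit_multinomial(x, y)
  oracle <- bruteforce_multinomial(x, y)
  expect_lt(max(abs(unname(fit$coef) - oracle)), 1e-5)
})

test_that("fitted values agree with an established multinomial fitter", {
  skip_if_not_installed("nnet")
  set.seed(97)
  n <- 500
  g <- sample(c("female", "male", "gd"), n, replace = TRUE,
              prob = c(0.5, 0.4, 0.1))
  y <- sample(1:3, n, replace = TRUE,
              prob = c(0.5, 0.3, 0.2))
  y[g == "gd" & runif(n) < 0.5] <- 3
  x <- stats::model.matrix(~ factor(g))
  fit <- fit_multinomial(x, y)
  ref <- nnet::multinom(factor(y) ~ factor(g), trace = FALSE,
                        reltol = 1e-14)
  expect_equal(unname(fit$coef), unname(t(stats::coef(ref))),
               tolerance = 1e-4)
})

test_that("a null predictor stays within three standard errors of zero", {
  set.seed(99)
  n <- 5000
  x <- cbind(1, rbinom(n, 1, 0.5))
  y <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  fit <- fit_multinomial(x, y)
  for (j in 1:2) {
    idx <- (j - 1) * 2 + 2
    se <- sqrt(fit$vcov[idx, idx])
    expect_lt(abs(fit$coef[2, j]), 3 * se)
  }
})

test_that("re-basing the reference category leaves fitted probabilities unchanged", {
  set.seed(101)
  n <- 300
  x <- cbind(1, rnorm(n))
  y <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.35, 0.25))
  f1 <- fit_multinomial(x, y, outcome_ref = 1)
  f2 <- fit_multinomial(x, y, outcome_ref = 2)
  p1 <- predict(f1, x)[, c("1", "2", "3")]
  p2 <- predict(f2, x)[, c("1", "2", "3")]
  expect_lt(max(abs(p1 - p2)), 1e-10)
})

test_that("encode_design applies declared references and the joint IRSAD term", {
  set.seed(115)
  lv <- youthcomplexity:::demographic_levels()
  df <- tibble::as_tibble(lapply(lv, function(x) {
    sample(rep(x, length.out = 60))
  }))
  x <- encode_design(df, model_spec())
  expect_true("(Intercept)" %in% colnames(x))
  expect_false(any(grepl("female", colnames(x)))) # reference absorbed
  # full joint term carries the 4 interaction columns
  expect_equal(sum(grepl(":", colnames(x))), 4)
  x2 <- encode_design(df, model_spec(irsad_by_remoteness = FALSE))
  expect_equal(ncol(x2), ncol(x) - 4)
  expect_error(
    encode_design(df[df$gender != "female", ], model_spec()),
    "absent from predictor"
  )
  expect_error(
    encode_design(df["gender"], model_spec()),
    "lack predictor"
  )
})

test_that("pooling identical datasets equals the single fit; Rubin arithmetic on the log scale", {
  set.seed(103)
  n <- 400
  df <- tibble::tibble(gender = sample(c("female", "male"), n, replace = TRUE))
  y <- sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4))
  spec <- model_spec(outcome_ref = 1, predictors = list(gender = "female"))
  single <- fit_pooled(df, y, spec)
  dup <- fit_pooled(list(df, df), y, spec)
  expect_equal(dup$table$estimate, single$table$estimate, tolerance = 1e-12)
  expect_equal(dup$table$rrr, single$table$rrr, tolerance = 1e-12)
  # worked Rubin example on the pooled scale
  ps <- pool_scalars(c(0.9, 1.1), c(0.04, 0.04))
  expect_equal(ps$estimate, 1.0)
  expect_equal(ps$total_variance, 0.04 + 1.5 * 0.01 * 2, tolerance = 1e-12)
})

test_that("relative risk ratios render as percentage increases", {
  expect_equal(rrr_percent_increase(3.41), 241)
  expect_equal(rrr_percent_increase(1.85), 85)
  expect_equal(rrr_percent_increase(1), 0)
})

test_that("a planted gender effect is recovered on the generator's scale", {
  cfg <- generator_config(n_episodes = 20000, all_missing_fraction = 0,
                          centre_mixing = Inf, seed = 107)
  ep <- sample_clusters(cfg)
  spec <- model_spec(outcome_ref = 1)
  pm <- fit_pooled(ep, ep$.true_cluster, spec)
  row <- pm$table[pm$table$outcome == "4" &
                    pm$table$term == "gendergender_diverse", ]
  expect_lt(abs(row$estimate - log(3.41)), 3 * row$se)
  expect_true(row$ci_low < row$rrr & row$rrr < row$ci_high)
})
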