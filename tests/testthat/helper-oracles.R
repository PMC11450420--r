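# independent oracles, built before and kept independent of the estimators
# they check

# Brute-force tetrachoric: maximise the multinomial likelihood over a dense
# rho grid (step 1e-4), with rectangle probabilities from a cumulative
# trapezoid integration of the bivariate-normal density along the
# correlation path (an identity independent of the package's adaptive
# quadrature).
grid_tetrachoric <- function(counts, step = 1e-4) {
  counts <- as.matrix(counts)
  if (any(counts == 0)) counts <- counts + 0.5
  n <- sum(counts)
  a <- qnorm(sum(counts[1, ]) / n)
  b <- qnorm(sum(counts[, 1]) / n)
  rs <- seq(-0.999, 0.999, by = step)
  dens <- exp(-(a^2 - 2 * rs * a * b + b^2) / (2 * (1 - rs^2))) /
    (2 * pi * sqrt(1 - rs^2))
  i0 <- which.min(abs(rs))
  # cumulative trapezoid outward from rho = 0
  cum <- numeric(length(rs))
  if (i0 < length(rs)) {
    inc <- (dens[(i0 + 1):length(rs)] + dens[i0:(length(rs) - 1)]) / 2 * step
    cum[(i0 + 1):length(rs)] <- cumsum(inc)
  }
  if (i0 > 1) {
    dec <- (dens[(i0 - 1):1] + dens[i0:2]) / 2 * step
    cum[(i0 - 1):1] <- -cumsum(dec)
  }
  p00 <- pnorm(a) * pnorm(b) + cum
  p01 <- pnorm(a) - p00
  p10 <- pnorm(b) - p00
  p11 <- 1 - pnorm(a) - pnorm(b) + p00
  ll <- counts[1, 1] * log(pmax(p00, 1e-12)) +
    counts[1, 2] * log(pmax(p01, 1e-12)) +
    counts[2, 1] * log(pmax(p10, 1e-12)) +
    counts[2, 2] * log(pmax(p11, 1e-12))
  rs[which.max(ll)]
}

# closed form for median splits: rho = sin(2 * pi * (p11 - 1/4))
median_split_rho <- function(p11) sin(2 * pi * (p11 - 0.25))

# direct numerical maximisation of the multinomial log-likelihood (BFGS on
# the flattened coefficient vector), independent of the Newton solver
bruteforce_multinomial <- function(x, y) {
  y <- factor(y)
  k <- nlevels(y)
  p <- ncol(x)
  yi <- as.integer(y)
  negll <- function(par) {
    beta <- matrix(par, p, k - 1)
    eta <- cbind(0, x %*% beta)
    eta <- eta - apply(eta, 1, max)
    pr <- exp(eta) / rowSums(exp(eta))
    -sum(log(pmax(pr[cbind(seq_along(yi), yi)], 1e-300)))
  }
  fit <- stats::optim(rep(0, p * (k - 1)), negll, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  matrix(fit$par, p, k - 1)
}

# ARI from first principles via the pair-counting definition (O(n^2)),
# usable only on tiny partitions
pair_counting_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - expected) / (max_index - expected)
}
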