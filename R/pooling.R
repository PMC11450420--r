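#' Pool a scalar estimate across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and variances: the pooled
#' estimate is the mean, the between-imputation variance is the sample
#' variance of the estimates, and the total variance is
#' `within + (1 + 1/m) * between`. Degrees of freedom follow Barnard-Rubin
#' when a finite complete-data df is supplied, and the classical
#' `(m - 1) / lambda^2` otherwise. The 95% interval uses the t reference
#' with those df (normal when the between-imputation variance is zero).
#'
#' @param estimates length-m numeric vector of per-imputation estimates.
#' @param variances length-m numeric vector of per-imputation (squared
#'   standard error) variances.
#' @param conf confidence level, default 0.95.
#' @param dfcom complete-data degrees of freedom (e.g. `n - p`); `Inf` gives
#'   the classical large-sample Rubin df.
#' @return object of class `pooled_scalar`: estimate, within_variance,
#'   between_variance, total_variance, df, ci_low, ci_high, m.
#' @export
pool_scalars <- function(estimates, variances, conf = 0.95, dfcom = Inf) {
  m <- length(estimates)
  if (m < 2) stop("pooling requires m >= 2 imputations", call. = FALSE)
  if (length(variances) != m || any(variances < 0)) {
    stop("variances must be length m and non-negative", call. = FALSE)
  }
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- stats::var(estimates)
  total <- ubar + (1 + 1 / m) * b

  if (b <= 0 || total <= 0) {
    df <- Inf
  } else {
    riv <- (1 + 1 / m) * b / ubar
    lambda <- if (is.finite(riv)) riv / (1 + riv) else 1
    lambda <- max(lambda, 1e-12)
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  }
  alpha <- 1 - conf
  crit <- if (is.finite(df)) stats::qt(1 - alpha / 2, df) else
    stats::qnorm(1 - alpha / 2)
  half <- crit * sqrt(total)
  structure(
    list(
      estimate = qbar, within_variance = ubar, between_variance = b,
      total_variance = total, df = df,
      ci_low = qbar - half, ci_high = qbar + half, m = m
    ),
    class = "pooled_scalar"
  )
}

#' @export
print.pooled_scalar <- function(x, ...) {
  cat(sprintf(
    "<pooled_scalar> %.4g (95%% CI %.4g to %.4g), m = %d, df = %.1f\n",
    x$estimate, x$ci_low, x$ci_high, x$m, x$df
  ))
  invisible(x)
}

#' Pool correlations across imputations on the Fisher-z scale
#'
#' Correlations are variance-stabilised with `atanh` before averaging and
#' back-transformed, the standard treatment for pooling correlation
#' matrices over imputed datasets.
#'
#' @param rhos numeric vector of correlations (NAs tolerated).
#' @param na_majority if more than half the entries are `NA`, return `NA`.
#' @return pooled correlation.
#' @export
pool_fisher_z <- function(rhos, na_majority = TRUE) {
  ok <- !is.na(rhos)
  if (na_majority && sum(ok) <= length(rhos) / 2) return(NA_real_)
  if (!any(ok)) return(NA_real_)
  z <- atanh(pmin(pmax(rhos[ok], -0.999), 0.999))
  tanh(mean(z))
}
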