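#' Specify the cluster-membership regression model
#'
#' Declares the outcome reference category and the categorical predictors
#' with their reference levels. Defaults mirror the complexity analysis:
#' low complexity as the outcome reference, female as the gender reference,
#' the youngest age band, non-Indigenous, non-CALD, low-IRSAD and
#' major-city references, and IRSAD considered jointly with remoteness via
#' a full interaction.
#'
#' @param outcome_ref reference outcome category (cluster label or name).
#' @param predictors named list mapping predictor columns to their
#'   reference level.
#' @param irsad_by_remoteness include the IRSAD x remoteness interaction.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome_ref = 1,
                       predictors = list(
                         gender = "female",
                         age_group = "12-14",
                         indigenous = "no",
                         cald = "no",
                         irsad_tertile = "low",
                         remoteness = "major_city"
                       ),
                       irsad_by_remoteness = TRUE) {
  structure(
    list(outcome_ref = outcome_ref, predictors = predictors,
         irsad_by_remoteness = irsad_by_remoteness),
    class = "model_spec"
  )
}

#' Encode a covariate table into a dummy design matrix
#'
#' Dummy (treatment) coding with the reference levels declared in the
#' [model_spec()]; no standardisation. The IRSAD-by-remoteness joint term
#' enters as a full interaction when requested.
#'
#' @param covariates data frame holding the spec's predictor columns.
#' @param spec a [model_spec()].
#' @return design matrix including an intercept column.
#' @export
encode_design <- function(covariates, spec = model_spec()) {
  used <- names(spec$predictors)
  missing_cols <- setdiff(used, names(covariates))
  if (length(missing_cols)) {
    abort_config("covariates lack predictor column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(covariates[used], stringsAsFactors = FALSE)
  for (nm in used) {
    ref <- spec$predictors[[nm]]
    if (!ref %in% df[[nm]]) {
      abort_config("reference level '%s' absent from predictor '%s'", ref, nm)
    }
    df[[nm]] <- stats::relevel(factor(df[[nm]]), ref = ref)
  }
  main <- setdiff(used, c("irsad_tertile", "remoteness"))
  terms <- main
  if (all(c("irsad_tertile", "remoteness") %in% used)) {
    terms <- c(terms, if (spec$irsad_by_remoteness)
      "irsad_tertile * remoteness" else c("irsad_tertile", "remoteness"))
  } else {
    terms <- c(terms, intersect(used, c("irsad_tertile", "remoteness")))
  }
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  x <- stats::model.matrix(form, df)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    abort_config("design matrix is rank deficient (%d < %d columns)",
                 qrx$rank, ncol(x))
  }
  x
}

# multinomial log-likelihood pieces: eta has K-1 columns (reference = 0)
multinom_prob <- function(x, beta) {
  eta <- cbind(0, x %*% beta)
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Maximum-likelihood multinomial logistic regression
#'
#' Newton-Raphson fit with step-halving on the log-likelihood, run to a
#' gradient max-norm below `1e-8` (at most 200 iterations). The covariance
#' is the inverse observed information. Quasi-separation (non-convergence
#' or exploding coefficients) triggers one warning-logged retry with a
#' ridge penalty of `1e-6`.
#'
#' @param design numeric design matrix including an intercept column (see
#'   [encode_design()]).
#' @param labels outcome vector; its first factor level (or the
#'   `outcome_ref` given) is the reference category.
#' @param outcome_ref reference outcome category.
#' @param ridge optional L2 penalty (used internally for the retry).
#' @param tol gradient max-norm convergence tolerance.
#' @return object of class `multinom_fit`: `coef` (p x (K-1) matrix), `vcov`
#'   (over `vec(coef)`), `loglik`, `categories`, `converged`, `iterations`.
#' @export
fit_multinomial <- function(design, labels, outcome_ref = NULL, ridge = 0,
                            tol = 1e-8) {
  x <- as.matrix(design)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- factor(labels)
  if (!is.null(outcome_ref)) y <- stats::relevel(y, ref = as.character(outcome_ref))
  lev <- levels(y)
  k <- length(lev)
  if (k < 2) abort_config("outcome needs at least 2 categories")
  if (any(tabulate(as.integer(y), k) == 0)) {
    abort_config("every outcome category needs at least one observation")
  }
  n <- nrow(x)
  p <- ncol(x)
  yind <- matrix(0, n, k)
  yind[cbind(seq_len(n), as.integer(y))] <- 1
  yind <- yind[, -1, drop = FALSE] # non-reference indicators

  npar <- p * (k - 1)
  beta <- matrix(0, p, k - 1)
  loglik <- function(beta) {
    pr <- multinom_prob(x, beta)
    sum(log(pmax(pr[cbind(seq_len(n), as.integer(y))], 1e-300))) -
      0.5 * ridge * sum(beta^2)
  }
  ll <- loglik(beta)
  converged <- FALSE
  grad_norm <- Inf
  it <- 0
  while (it < 200) {
    it <- it + 1
    pr <- multinom_prob(x, beta)[, -1, drop = FALSE]
    grad <- crossprod(x, yind - pr) - ridge * beta
    grad_norm <- max(abs(grad))
    if (grad_norm < tol) {
      converged <- TRUE
      break
    }
    hess <- matrix(0, npar, npar)
    for (j in seq_len(k - 1)) {
      for (l in j:(k - 1)) {
        w <- if (j == l) pr[, j] * (1 - pr[, j]) else -pr[, j] * pr[, l]
        blk <- crossprod(x * w, x)
        rj <- (j - 1) * p + seq_len(p)
        rl <- (l - 1) * p + seq_len(p)
        hess[rj, rl] <- blk
        hess[rl, rj] <- t(blk)
      }
    }
    hess <- hess + diag(ridge + 1e-12, npar)
    step <- tryCatch(solve(hess, as.vector(grad)), error = function(e) {
      solve(hess + diag(1e-8, npar), as.vector(grad))
    })
    # step-halving keeps the likelihood non-decreasing
    alpha <- 1
    repeat {
      cand <- beta + alpha * matrix(step, p, k - 1)
      ll_cand <- loglik(cand)
      if (ll_cand >= ll - 1e-12 || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    beta <- cand
    ll <- ll_cand
  }

  if (!converged || max(abs(beta)) > 30) {
    if (ridge == 0) {
      warning(sprintf(
        "possible quasi-separation (gradient norm %.2e); retrying with ridge 1e-6",
        grad_norm
      ), call. = FALSE)
      return(fit_multinomial(design, labels,
                             outcome_ref = lev[1], ridge = 1e-6, tol = tol))
    }
    if (!converged) {
      stop(sprintf("multinomial fit did not converge; final gradient norm %.2e",
                   grad_norm), call. = FALSE)
    }
  }

  pr <- multinom_prob(x, beta)[, -1, drop = FALSE]
  hess <- matrix(0, npar, npar)
  for (j in seq_len(k - 1)) {
    for (l in j:(k - 1)) {
      w <- if (j == l) pr[, j] * (1 - pr[, j]) else -pr[, j] * pr[, l]
      blk <- crossprod(x * w, x)
      rj <- (j - 1) * p + seq_len(p)
      rl <- (l - 1) * p + seq_len(p)
      hess[rj, rl] <- blk
      hess[rl, rj] <- t(blk)
    }
  }
  vcov <- tryCatch(solve(hess), error = function(e) {
    solve(hess + diag(1e-8, npar))
  })
  dimnames(beta) <- list(colnames(x), lev[-1])
  par_names <- as.vector(outer(colnames(x), lev[-1],
                               function(a, b) paste(b, a, sep = ":")))
  dimnames(vcov) <- list(par_names, par_names)
  structure(
    list(coef = beta, vcov = vcov, loglik = ll, categories = lev,
         converged = converged, iterations = it, n = n),
    class = "multinom_fit"
  )
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat(sprintf(
    "<multinom_fit> %d categories (ref '%s'), %d coefficients, loglik %.2f (%d iterations)\n",
    length(x$categories), x$categories[1], length(x$coef), x$loglik,
    x$iterations
  ))
  invisible(x)
}

#' Fitted category probabilities of a multinomial fit
#'
#' @param object a `multinom_fit`.
#' @param newdata design matrix (same encoding as the fit).
#' @param ... unused.
#' @return n x K matrix of probabilities, columns named by category.
#' @export
predict.multinom_fit <- function(object, newdata, ...) {
  pr <- multinom_prob(as.matrix(newdata), object$coef)
  colnames(pr) <- object$categories
  pr
}

#' Fit the cluster-membership model and pool across imputed datasets
#'
#' Fits the multinomial model once per supplied dataset and pools each
#' coefficient with Rubin's rules on the log-RRR scale. In the standard
#' pipeline the demographics are complete and the consensus labels fixed,
#' so one complete-data fit is supplied and the pooled output reduces to it
#' exactly; pooling engages when the model involves imputed quantities
#' (one covariate table per completed dataset).
#'
#' @param datasets a covariate data frame, or a list of m such data frames
#'   (one per imputed dataset, identical row order).
#' @param labels outcome vector (consensus cluster labels).
#' @param spec a [model_spec()].
#' @return object of class `pooled_model`: tibble with outcome category,
#'   term, log-RRR estimate, standard error, df, RRR and 95% CI.
#' @export
fit_pooled <- function(datasets, labels, spec = model_spec()) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  m <- length(datasets)
  fits <- lapply(datasets, function(d) {
    fit_multinomial(encode_design(d, spec), labels,
                    outcome_ref = spec$outcome_ref)
  })
  cats <- fits[[1]]$categories
  for (f in fits) {
    if (!identical(f$categories, cats)) {
      stop("outcome categories differ across imputed datasets", call. = FALSE)
    }
  }
  terms <- rownames(fits[[1]]$coef)
  p <- length(terms)
  k1 <- length(cats) - 1
  n <- fits[[1]]$n
  dfcom <- n - p

  rows <- list()
  for (j in seq_len(k1)) {
    for (t in seq_len(p)) {
      est <- vapply(fits, function(f) f$coef[t, j], numeric(1))
      vr <- vapply(fits, function(f) {
        idx <- (j - 1) * p + t
        f$vcov[idx, idx]
      }, numeric(1))
      if (m >= 2) {
        ps <- pool_scalars(est, vr, dfcom = dfcom)
      } else {
        crit <- stats::qnorm(0.975)
        ps <- list(estimate = est, total_variance = vr, df = dfcom,
                   ci_low = est - crit * sqrt(vr),
                   ci_high = est + crit * sqrt(vr),
                   within_variance = vr, between_variance = 0)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        outcome = cats[j + 1], term = terms[t],
        estimate = ps$estimate, se = sqrt(ps$total_variance), df = ps$df,
        rrr = exp(ps$estimate),
        ci_low = exp(ps$ci_low), ci_high = exp(ps$ci_high)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(
    list(table = out, reference = cats[1], m = m, spec = spec),
    class = "pooled_model"
  )
}

#' @export
print.pooled_model <- function(x, ...) {
  cat(sprintf(
    "<pooled_model> %d terms x %d outcome categories vs reference '%s' (m = %d)\n",
    length(unique(x$table$term)), length(unique(x$table$outcome)),
    x$reference, x$m
  ))
  print(x$table, n = 12)
  invisible(x)
}

#' Render a relative risk ratio as a percentage increase
#'
#' An RRR of 3.41 corresponds to a 241% higher relative risk.
#'
#' @param rrr relative risk ratio(s).
#' @return percentage increase `(rrr - 1) * 100`.
#' @export
rrr_percent_increase <- function(rrr) (rrr - 1) * 100

#' Write a pooled model as a results table (CSV) and JSON
#'
#' @param model a `pooled_model`.
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_pooled_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "model_rrr.csv"),
             json = file.path(dir, "model_rrr.json"))
  data.table::fwrite(model$table, paths["table"])
  jsonlite::write_json(
    list(reference = model$reference, m = model$m, table = model$table),
    paths["json"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
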