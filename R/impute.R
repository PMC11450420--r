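#' Ridge-stabilised logistic regression by IRLS
#'
#' Main-effects logistic fit with a small L2 penalty on the non-intercept
#' coefficients, used as the conditional model of the chained-equation
#' imputer. The penalty keeps the fit defined under perfect separation and
#' sparse items.
#'
#' @param x numeric design matrix (no intercept column; one is added).
#' @param y 0/1 response.
#' @param ridge penalty on squared coefficients (intercept unpenalised).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return list with `coef`, `cov` (inverse penalised information) and
#'   `converged`.
#' @keywords internal
ridge_logistic <- function(x, y, ridge = 1e-4, max_iter = 50, tol = 1e-8) {
  x <- cbind(`(Intercept)` = 1, as.matrix(x))
  p <- ncol(x)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  beta <- numeric(p)
  beta[1] <- qlogis(min(max(mean(y), 1 / (length(y) + 2)),
                        1 - 1 / (length(y) + 2)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(x * w, x) + pen
    score <- crossprod(x, y - mu) - pen %*% beta
    delta <- tryCatch(solve(info, score), error = function(e) {
      solve(info + diag(1e-6, p), score)
    })
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(x * w, x) + pen
  cov <- tryCatch(solve(info), error = function(e) solve(info + diag(1e-6, p)))
  list(coef = beta, cov = cov, converged = converged)
}

new_imputation_set <- function(completed, episode_ids, indicator_names,
                               rng_state = list()) {
  stopifnot(length(completed) >= 1)
  structure(
    list(
      completed = completed, m = length(completed),
      episode_ids = episode_ids, indicator_names = indicator_names,
      rng_state = rng_state
    ),
    class = "imputation_set"
  )
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d completed datasets of %d x %d\n",
              x$m, nrow(x$completed[[1]]), ncol(x$completed[[1]])))
  invisible(x)
}

#' Wrap one or more complete binary matrices as an imputation set
#'
#' Convenience for running the consensus machinery on complete data (m = 1)
#' or on externally produced completed datasets.
#'
#' @param values a complete 0/1 matrix, or list of such matrices.
#' @param episode_ids optional row identifiers.
#' @return an `imputation_set`.
#' @export
as_imputation_set <- function(values, episode_ids = NULL) {
  if (!is.list(values)) values <- list(values)
  values <- lapply(values, function(v) {
    v <- as.matrix(v)
    stopifnot(!anyNA(v), all(v %in% c(0, 1)))
    storage.mode(v) <- "integer"
    v
  })
  if (is.null(episode_ids)) episode_ids <- seq_len(nrow(values[[1]]))
  new_imputation_set(values, episode_ids,
                     colnames(values[[1]]) %||%
                       paste0("item", seq_len(ncol(values[[1]]))))
}

#' Multiply impute missing binary indicators by chained equations
#'
#' Each missing cell is filled by iterated conditional logistic draws: the
#' matrix is initialised by observed-prevalence draws, then swept a fixed
#' number of times over the items in ascending-missingness order. At each
#' sweep the item's conditional model (main-effects ridge logistic on the
#' other items, plus optional covariates) is refitted on the currently
#' completed data restricted to rows where the item was observed,
#' coefficients are drawn from their approximate posterior, and missing
#' cells are redrawn as Bernoulli. Observed cells are never touched.
#'
#' @param m_in an `indicator_matrix` with no all-missing rows (run
#'   [exclusion_filter()] first).
#' @param m_count number of completed datasets, default 20.
#' @param covariates optional data frame of complete auxiliary covariates
#'   (factors allowed); off by default.
#' @param seed master seed; each imputation uses an independent substream.
#' @param sweeps chained-equation sweeps per imputation.
#' @param ridge L2 penalty of the conditional models.
#' @return an `imputation_set`; `rng_state` records the seeds and settings.
#' @export
impute_indicators <- function(m_in, m_count = 20, covariates = NULL,
                              seed = 1L, sweeps = 10, ridge = 1e-4) {
  stopifnot(inherits(m_in, "indicator_matrix"))
  vals <- m_in$values
  obs <- m_in$observed_mask
  n <- nrow(vals)
  if (any(rowSums(obs) == 0)) {
    stop("impute_indicators: all-missing rows present; apply exclusion_filter first",
         call. = FALSE)
  }
  n_obs <- colSums(obs)
  if (any(n_obs == 0)) {
    stop(sprintf("impute_indicators: indicator(s) with zero observed cases: %s",
                 paste(m_in$indicator_names[n_obs == 0], collapse = ", ")),
         call. = FALSE)
  }
  cov_mat <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = TRUE)
    covariates[] <- lapply(covariates, function(x) {
      if (is.character(x)) factor(x) else x
    })
    cov_mat <- stats::model.matrix(~., covariates)[, -1, drop = FALSE]
    stopifnot(nrow(cov_mat) == n)
  }

  item_order <- order(colSums(!obs))
  prev <- colSums(vals == 1L, na.rm = TRUE) / n_obs
  seeds <- derive_seeds(seed, m_count)

  completed <- lapply(seq_len(m_count), function(i) {
    with_seed(seeds[i], {
      cur <- vals
      for (j in seq_len(ncol(cur))) {
        miss <- !obs[, j]
        if (any(miss)) {
          cur[miss, j] <- as.integer(runif(sum(miss)) < prev[j])
        }
      }
      any_missing <- any(!obs)
      if (any_missing) {
        for (s in seq_len(sweeps)) {
          for (j in item_order) {
            miss <- !obs[, j]
            if (!any(miss)) next
            x <- cur[, -j, drop = FALSE]
            if (!is.null(cov_mat)) x <- cbind(x, cov_mat)
            fit <- ridge_logistic(x[!miss, , drop = FALSE], cur[!miss, j],
                                  ridge = ridge)
            if (!fit$converged) {
              warning(sprintf(
                "conditional model for '%s' not fully converged; using ridge-stabilised iterate",
                m_in$indicator_names[j]
              ), call. = FALSE)
            }
            beta <- drop(fit$coef + chol_mvn_draw(fit$cov))
            p_miss <- plogis(drop(cbind(1, x[miss, , drop = FALSE]) %*% beta))
            cur[miss, j] <- as.integer(runif(sum(miss)) < p_miss)
          }
        }
      }
      cur
    })
  })

  new_imputation_set(
    completed, m_in$episode_ids, m_in$indicator_names,
    rng_state = list(master_seed = seed, stream_seeds = seeds,
                     sweeps = sweeps, ridge = ridge,
                     covariates = !is.null(cov_mat))
  )
}

# one draw from N(0, cov) via the Cholesky root (jittered if needed)
chol_mvn_draw <- function(cov) {
  p <- ncol(cov)
  ch <- tryCatch(chol(cov), error = function(e) chol(cov + diag(1e-8, p)))
  drop(crossprod(ch, rnorm(p)))
}

#' Serialise / load an imputation set
#'
#' One CSV per completed dataset plus a JSON manifest recording m, seeds and
#' model settings.
#'
#' @param imps an `imputation_set`.
#' @param dir output directory.
#' @return `write_imputation_set()` the manifest path invisibly;
#'   `read_imputation_set()` an `imputation_set`.
#' @export
write_imputation_set <- function(imps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(imps$m)
  for (i in seq_len(imps$m)) {
    files[i] <- file.path(dir, sprintf("imputation_%03d.csv", i))
    df <- data.table::data.table(episode_id = imps$episode_ids)
    mat <- imps$completed[[i]]
    for (j in seq_along(imps$indicator_names)) {
      df[[imps$indicator_names[j]]] <- mat[, j]
    }
    data.table::fwrite(df, files[i])
  }
  manifest <- list(
    m = imps$m, files = basename(files),
    indicator_names = imps$indicator_names,
    rng_state = imps$rng_state
  )
  path <- file.path(dir, "imputations.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_imputation_set
#' @export
read_imputation_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "imputations.json"),
                                  simplifyVector = TRUE)
  completed <- lapply(manifest$files, function(f) {
    df <- data.table::fread(file.path(dir, f))
    as.matrix(df[, manifest$indicator_names, with = FALSE])
  })
  ids <- data.table::fread(file.path(dir, manifest$files[1]))$episode_id
  new_imputation_set(completed, ids, manifest$indicator_names,
                     rng_state = as.list(manifest$rng_state))
}
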