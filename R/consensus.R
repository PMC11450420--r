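#' k-means++ seeding
#'
#' Chooses initial centres by the k-means++ rule: first centre uniform,
#' subsequent centres with probability proportional to squared distance to
#' the nearest chosen centre.
#'
#' @param x numeric matrix.
#' @param k number of centres.
#' @return k x ncol(x) matrix of initial centres.
#' @keywords internal
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    if (all(d2 <= 0)) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

# one base k-means run with k-means++ init and a single re-seed on failure
base_kmeans <- function(x, k) {
  run <- function() {
    centers <- kmeanspp_centers(x, k)
    centers <- centers[!duplicated(centers), , drop = FALSE]
    stats::kmeans(x, centers = centers, iter.max = 100,
                  algorithm = "Lloyd")$cluster
  }
  cl <- tryCatch(suppressWarnings(run()), error = function(e) NULL)
  if (is.null(cl)) cl <- tryCatch(suppressWarnings(run()),
                                  error = function(e) NULL)
  if (is.null(cl)) {
    # accept a reduced-k run for this replicate
    cl <- suppressWarnings(stats::kmeans(x, centers = max(k - 1, 1),
                                         iter.max = 100)$cluster)
  }
  cl
}

#' K-means consensus clustering over an imputation set
#'
#' For every completed dataset and each of `R` replicates, a subsample of
#' `ceiling(p * n)` episodes (without replacement) is clustered by k-means
#' (k-means++ initialisation, Euclidean metric on the 0/1 indicators). Pair
#' co-clustering counts are normalised by pair co-sampling counts to give
#' the consensus matrix; the final partition is the average-linkage
#' hierarchical cut of `1 - consensus` at k, with labels renumbered so that
#' cluster 1 carries the lowest and cluster k the highest mean indicator
#' burden.
#'
#' @param imps an `imputation_set` (use [as_imputation_set()] for complete
#'   data).
#' @param k number of clusters (`2 <= k <= n/10`).
#' @param R subsample replicates per imputation, default 100.
#' @param p subsample fraction in `[0.5, 1]`, default 0.8.
#' @param seed integer seed.
#' @param scale_items standardise indicator columns before k-means; off by
#'   default since all items share the 0/1 scale.
#' @param pac_window consensus window counted as ambiguous, default
#'   `c(0.1, 0.9)`.
#' @return object of class `consensus_result`: consensus matrix, ordered
#'   `labels`, `pac`, `cdf_points`, per-cluster mean burden and settings.
#' @export
consensus_kmeans <- function(imps, k, R = 100, p = 0.8, seed = 1L,
                             scale_items = FALSE,
                             pac_window = c(0.1, 0.9)) {
  stopifnot(inherits(imps, "imputation_set"))
  n <- nrow(imps$completed[[1]])
  if (k < 2 || k > n / 10) {
    abort_config("k must satisfy 2 <= k <= n/10 (got k = %s, n = %d)", k, n)
  }
  if (p < 0.5 || p > 1) abort_config("subsample fraction p must be in [0.5, 1]")
  if (R < 10) abort_config("R must be at least 10 resamples per imputation")

  n_sub <- ceiling(p * n)
  conn <- matrix(0, n, n)
  cosamp <- matrix(0, n, n)
  seeds <- derive_seeds(seed, imps$m)

  for (i in seq_len(imps$m)) {
    x <- imps$completed[[i]] * 1.0
    if (scale_items) x <- scale(x)
    with_seed(seeds[i], {
      for (r in seq_len(R)) {
        idx <- if (n_sub == n) seq_len(n) else sample.int(n, n_sub)
        cl <- base_kmeans(x[idx, , drop = FALSE], k)
        memb <- matrix(0, n, max(cl))
        memb[cbind(idx, cl)] <- 1
        conn <- conn + tcrossprod(memb)
        s <- numeric(n)
        s[idx] <- 1
        cosamp <- cosamp + tcrossprod(s)
      }
    })
  }

  never <- cosamp == 0
  consensus <- conn / pmax(cosamp, 1)
  if (any(never)) {
    fill <- mean(consensus[!never & upper.tri(consensus)])
    consensus[never] <- fill
    message(sprintf(
      "consensus_kmeans: %d never-co-sampled pairs filled with global mean %.3f",
      sum(never[upper.tri(never)]), fill
    ))
  }
  consensus <- (consensus + t(consensus)) / 2
  diag(consensus) <- 1

  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  raw_labels <- stats::cutree(hc, k = k)

  # severity ordering by mean indicator burden (averaged over imputations)
  burden <- Reduce(`+`, lapply(imps$completed, rowSums)) / imps$m
  means <- tapply(burden, raw_labels, mean)
  ord <- order(means)
  relabel <- integer(length(means))
  relabel[as.integer(names(means))[ord]] <- seq_along(ord)
  labels <- relabel[raw_labels]

  upper <- consensus[upper.tri(consensus)]
  pac <- mean(upper > pac_window[1] & upper < pac_window[2])
  qs <- seq(0, 1, by = 0.01)
  cdf_points <- tibble::tibble(
    consensus = qs,
    cdf = stats::ecdf(upper)(qs)
  )

  structure(
    list(
      k = k, consensus = consensus, labels = labels, pac = pac,
      cdf_points = cdf_points,
      cluster_burden = as.numeric(sort(means)),
      settings = list(R = R, p = p, seed = seed, m = imps$m,
                      scale_items = scale_items, pac_window = pac_window),
      episode_ids = imps$episode_ids
    ),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> k = %d, n = %d, PAC = %.3f\n  cluster sizes: %s\n",
    x$k, length(x$labels), x$pac,
    paste(tabulate(x$labels, x$k), collapse = ", ")
  ))
  invisible(x)
}

#' Consensus diagnostics over a range of k
#'
#' Runs [consensus_kmeans()] for each candidate k and reports the
#' proportion of ambiguous clustering (PAC). The recommended k minimises
#' PAC, but the return is advisory: the caller may override on clinical
#' grounds, and both the recommendation and any override are recorded
#' separately by the pipeline. A `no_structure` flag is raised when even
#' the best PAC is high.
#'
#' @inheritParams consensus_kmeans
#' @param k_range integer vector of candidate k.
#' @param no_structure_pac PAC level above which "no stable split" is
#'   flagged, default 0.4.
#' @return list with `diagnostics` tibble (k, pac), `recommended_k`,
#'   `no_structure`, and the per-k `results`.
#' @export
select_k <- function(imps, k_range = 2:6, R = 100, p = 0.8, seed = 1L,
                     no_structure_pac = 0.4) {
  k_range <- sort(unique(as.integer(k_range)))
  seeds <- derive_seeds(seed + 13L, length(k_range))
  results <- lapply(seq_along(k_range), function(i) {
    consensus_kmeans(imps, k_range[i], R = R, p = p, seed = seeds[i])
  })
  pac <- vapply(results, `[[`, numeric(1), "pac")
  diagnostics <- tibble::tibble(k = k_range, pac = pac)
  best <- k_range[which.min(pac)]
  list(
    diagnostics = diagnostics,
    recommended_k = best,
    no_structure = min(pac) > no_structure_pac,
    results = stats::setNames(results, paste0("k", k_range))
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table;
#' permutation invariant, 1 for identical partitions.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("partitions must have equal length", call. = FALSE)
  }
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(labels_a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Write consensus artefacts as delimited text and JSON
#'
#' @param res a `consensus_result`.
#' @param dir output directory.
#' @param save_matrix write the full consensus matrix CSV (can be large).
#' @return named vector of written paths, invisibly.
#' @export
write_consensus_result <- function(res, dir, save_matrix = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(labels = file.path(dir, "cluster_labels.csv"),
             diagnostics = file.path(dir, "consensus_diagnostics.json"))
  data.table::fwrite(
    data.table::data.table(episode_id = res$episode_ids, cluster = res$labels),
    paths["labels"]
  )
  jsonlite::write_json(
    list(k = res$k, pac = res$pac, settings = res$settings,
         cluster_burden = res$cluster_burden,
         cluster_sizes = tabulate(res$labels, res$k),
         cdf_points = res$cdf_points),
    paths["diagnostics"], auto_unbox = TRUE, digits = NA
  )
  if (save_matrix) {
    paths["consensus"] <- file.path(dir, "consensus_matrix.csv")
    data.table::fwrite(data.table::as.data.table(res$consensus),
                       paths["consensus"], col.names = FALSE)
  }
  invisible(paths)
}
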