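#' Standard bivariate normal rectangle probability
#'
#' `P(Z1 <= x, Z2 <= y)` for correlation `rho`, computed from the identity
#' reducing the double integral to a single integral of the bivariate
#' density over the correlation path, evaluated with adaptive quadrature at
#' absolute tolerance 1e-10. This is the likelihood kernel of the
#' tetrachoric estimator.
#'
#' @param x,y upper integration limits.
#' @param rho latent correlation in `(-1, 1)`.
#' @return the rectangle probability.
#' @export
pbvnorm <- function(x, y, rho) {
  stopifnot(abs(rho) < 1)
  base <- pnorm(x) * pnorm(y)
  if (rho == 0 || !is.finite(x) || !is.finite(y)) {
    if (!is.finite(x) || !is.finite(y)) {
      # degenerate margins: reduce to the univariate case
      if (x == Inf) return(pnorm(y))
      if (y == Inf) return(pnorm(x))
      return(0)
    }
    return(base)
  }
  dens <- function(r) {
    exp(-(x^2 - 2 * r * x * y + y^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  }
  base + stats::integrate(dens, 0, rho, abs.tol = 1e-10,
                          rel.tol = 1e-10)$value
}

# cell probabilities (p00, p01, p10, p11) given thresholds a, b and rho;
# cell order matches a 2x2 table with rows = X in (0,1), cols = Y in (0,1)
tetra_cell_probs <- function(a, b, rho) {
  p00 <- pbvnorm(a, b, rho)
  pa <- pnorm(a)
  pb <- pnorm(b)
  p01 <- pa - p00
  p10 <- pb - p00
  p11 <- 1 - pa - pb + p00
  pmax(c(p00, p01, p10, p11), 1e-12)
}

#' Tetrachoric correlation of a 2x2 table
#'
#' Maximum-likelihood correlation of the latent bivariate-normal threshold
#' model: thresholds are fixed from the table margins by the inverse normal
#' and the correlation maximises the multinomial likelihood of the four
#' cells under the bivariate-normal rectangle probabilities. Tables with a
#' zero cell receive a 0.5 continuity correction to every cell; a zero
#' margin after correction is undefined and returns `NA`.
#'
#' @param counts 2x2 table of non-negative counts; rows index the first
#'   variable (0, 1), columns the second.
#' @return ML estimate of the latent correlation, clamped to
#'   `[-0.999, 0.999]`, or `NA` when undefined.
#' @export
tetrachoric <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0))
  if (any(counts == 0)) counts <- counts + 0.5
  n <- sum(counts)
  if (n < 10) stop("table total must be at least 10 after correction",
                   call. = FALSE)
  row1 <- sum(counts[1, ])
  col1 <- sum(counts[, 1])
  if (row1 == 0 || col1 == 0 || row1 == n || col1 == n) return(NA_real_)
  a <- qnorm(row1 / n) # threshold for X (P(X = 0) = Phi(a))
  b <- qnorm(col1 / n)
  nvec <- c(counts[1, 1], counts[1, 2], counts[2, 1], counts[2, 2])
  negll <- function(rho) -sum(nvec * log(tetra_cell_probs(a, b, rho)))
  opt <- stats::optimize(negll, c(-0.999, 0.999), tol = 1e-7)
  max(min(opt$minimum, 0.999), -0.999)
}

# pairwise tetrachoric matrix of one complete 0/1 matrix
tetrachoric_matrix <- function(x) {
  p <- ncol(x)
  rho <- diag(1, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      tab <- table(factor(x[, i], levels = 0:1), factor(x[, j], levels = 0:1))
      r <- tryCatch(tetrachoric(tab), error = function(e) NA_real_)
      rho[i, j] <- rho[j, i] <- r
    }
  }
  dimnames(rho) <- list(colnames(x), colnames(x))
  rho
}

#' Pooled tetrachoric correlation network across imputations
#'
#' Estimates the full pairwise tetrachoric matrix within each completed
#' dataset and pools entries across imputations on the Fisher-z scale.
#' Pairs undefined in more than half the imputations are flagged missing.
#' Optionally attaches the multidimensional-scaling layout and edge list
#' for plotting.
#'
#' @param imps an `imputation_set` with `m >= 2` (a single complete dataset
#'   is also accepted and returned unpooled).
#' @param layout compute the 2-d MDS layout, default `TRUE`.
#' @return object of class `tetra_network`: `rho` (pooled matrix),
#'   `pooled_from` (m), `layout` (p x 2 or `NULL`), `edge_list` tibble.
#' @export
pooled_tetrachoric <- function(imps, layout = TRUE) {
  stopifnot(inherits(imps, "imputation_set"))
  mats <- lapply(imps$completed, tetrachoric_matrix)
  p <- ncol(mats[[1]])
  rho <- diag(1, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      rhos <- vapply(mats, function(m) m[i, j], numeric(1))
      rho[i, j] <- rho[j, i] <- if (imps$m >= 2) pool_fisher_z(rhos) else rhos[1]
    }
  }
  dimnames(rho) <- list(imps$indicator_names, imps$indicator_names)
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  edge_list <- tibble::tibble(
    source = imps$indicator_names[pairs[, 1]],
    target = imps$indicator_names[pairs[, 2]],
    rho = rho[pairs]
  )
  coords <- if (layout) mds_layout(rho) else NULL
  structure(
    list(rho = rho, pooled_from = imps$m, layout = coords,
         edge_list = edge_list),
    class = "tetra_network"
  )
}

#' @export
print.tetra_network <- function(x, ...) {
  top <- x$edge_list[order(-abs(x$edge_list$rho)), ][1, ]
  cat(sprintf(
    "<tetra_network> %d items pooled from %d dataset(s); strongest edge %s - %s (rho = %.2f)\n",
    ncol(x$rho), x$pooled_from, top$source, top$target, top$rho
  ))
  invisible(x)
}

# nearest-PSD repair by eigenvalue clipping, rescaled to unit diagonal
nearest_psd_corr <- function(rho, warn_change = 0.1) {
  e <- eigen((rho + t(rho)) / 2, symmetric = TRUE)
  if (min(e$values) >= -1e-12) return(rho)
  vals <- pmax(e$values, 0)
  r2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(pmax(diag(r2), 1e-12))
  r2 <- r2 / tcrossprod(d)
  diag(r2) <- 1
  max_change <- max(abs(r2 - rho))
  if (max_change > warn_change) {
    warning(sprintf(
      "positive-semidefinite repair changed an entry by %.3f", max_change
    ), call. = FALSE)
  }
  dimnames(r2) <- dimnames(rho)
  r2
}

#' Classical MDS layout of a correlation matrix
#'
#' Converts correlations to dissimilarities `sqrt(2 * (1 - rho))` after a
#' nearest-positive-semidefinite repair, then applies classical (Torgerson)
#' scaling to two dimensions. The output is centred and its orientation
#' fixed by a sign convention (first item's coordinates non-negative).
#'
#' @param rho symmetric correlation matrix with unit diagonal.
#' @return p x 2 coordinate matrix.
#' @export
mds_layout <- function(rho) {
  stopifnot(isSymmetric(unname(rho)), all(abs(diag(rho) - 1) < 1e-8))
  rho2 <- nearest_psd_corr(rho)
  d <- sqrt(pmax(2 * (1 - rho2), 0))
  coords <- stats::cmdscale(stats::as.dist(d), k = 2)
  if (ncol(coords) < 2) {
    coords <- cbind(coords, 0)[, 1:2, drop = FALSE]
  }
  coords <- sweep(coords, 2, colMeans(coords))
  for (j in 1:2) {
    pivot <- which(abs(coords[, j]) > 1e-12)[1]
    if (!is.na(pivot) && coords[pivot, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(rho)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Kruskal stress-0 of a layout against target dissimilarities
#'
#' @param d target dissimilarity matrix.
#' @param coords layout coordinates.
#' @return raw stress `sqrt(sum((d - dhat)^2) / sum(d^2))`.
#' @export
layout_stress <- function(d, coords) {
  dhat <- as.matrix(stats::dist(coords))
  d <- as.matrix(d)
  up <- upper.tri(d)
  sqrt(sum((d[up] - dhat[up])^2) / sum(d[up]^2))
}

#' Write network artefacts (edge list and layout) as delimited text
#'
#' @param net a `tetra_network`.
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_tetra_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(edges = file.path(dir, "network_edges.csv"),
             layout = file.path(dir, "network_layout.csv"))
  data.table::fwrite(net$edge_list, paths["edges"])
  layout_df <- data.table::data.table(
    item = rownames(net$layout),
    dim1 = net$layout[, 1], dim2 = net$layout[, 2]
  )
  data.table::fwrite(layout_df, paths["layout"])
  invisible(paths)
}
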