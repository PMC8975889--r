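#' Modified principal-component scores from top-loading genes
#'
#' Standard PCA is run on the centered normalized expression (cells as
#' observations). For each of the top two components, genes are ranked by
#' absolute loading and the component score is recomputed using only the
#' `n_top` largest-loading genes (all other loadings zeroed), which damps the
#' contribution of technical, low-loading genes. With `n_top >= #genes` the
#' scores equal the standard PC scores. When `weighted = FALSE` the signed,
#' unweighted sum of the centered expression of the top genes (sign taken
#' from the loading) is used instead.
#'
#' @param dataset a normalized [expression_dataset()].
#' @param cells cell identifiers (default all).
#' @param n_top genes retained per component (default 60).
#' @param weighted loading-weighted (default) or signed-sum scores.
#' @return matrix (cells x 2) of modified PC scores.
#' @export
modified_pc_scores <- function(dataset, cells = NULL, n_top = 60,
                               weighted = TRUE) {
  stopifnot(!is.null(dataset$norm), n_top >= 1)
  if (is.null(cells)) cells <- colnames(dataset$norm)
  stopifnot(length(cells) >= 3)
  x <- t(as.matrix(dataset$norm[, cells, drop = FALSE]))
  xc <- scale(x, center = TRUE, scale = FALSE)
  pc <- prcomp(xc, center = FALSE, rank. = 2)
  scores <- sapply(1:2, function(k) {
    load <- pc$rotation[, k]
    top <- order(-abs(load))[seq_len(min(n_top, length(load)))]
    w <- numeric(length(load))
    w[top] <- if (weighted) load[top] else sign(load[top])
    as.numeric(xc %*% w)
  })
  dimnames(scores) <- list(cells, c("PC1_mod", "PC2_mod"))
  scores
}

#' Fit a principal curve to 2D points and order cells along it
#'
#' Iterative principal-curve fit: the curve is initialized as the first
#' principal axis of the points; then the algorithm alternates (a) projecting
#' every point onto the current curve (polyline), taking the arc-length
#' position as lambda, and (b) smoothing each coordinate against lambda with a
#' cubic smoothing spline of `df` degrees of freedom. Iteration stops when
#' the relative change in mean squared projection distance drops below `tol`
#' or after `max_iter` iterations. The fit is deterministic.
#'
#' A low fixed `df` (default 5) keeps the curve a one-dimensional summary;
#' with data-driven smoothness (`df = NULL`, GCV) the self-consistency
#' iteration can collapse onto an interpolating curve, so the fixed default
#' is recommended.
#'
#' @param points numeric matrix (cells x 2), rownames = cell identifiers.
#' @param max_iter maximum iterations (default 50).
#' @param tol relative convergence tolerance on the mean squared projection
#'   distance (default 1e-4).
#' @param df spline degrees of freedom (default 5); `NULL` for GCV.
#' @return list of class `PseudoOrderResult`: `lambda` (named arc-length
#'   positions), `projection` (cells x 2 matrix of projected points), `curve`
#'   (ordered polyline), `dist_history` (mean squared projection distance per
#'   iteration), `converged`.
#' @export
fit_principal_curve <- function(points, max_iter = 50, tol = 1e-4, df = 5) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 5)
  if (all(apply(points, 2, sd) == 0)) stop("all points identical")
  ids <- rownames(points)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(points)))

  ctr <- colMeans(points)
  xc <- sweep(points, 2, ctr)
  v <- eigen(cov(xc), symmetric = TRUE)$vectors[, 1]
  lambda <- as.numeric(xc %*% v)
  # initial curve: the first principal axis itself
  ord <- order(lambda)
  curve <- sweep(outer(lambda[ord], v), 2, -ctr)
  proj <- .project_polyline(points, curve)
  lambda <- proj$lambda
  d2 <- mean(proj$dist2)
  hist <- d2
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    new_curve <- .smooth_curve(points, lambda, df)
    proj <- .project_polyline(points, new_curve)
    d2_new <- mean(proj$dist2)
    curve <- new_curve
    lambda <- proj$lambda
    hist <- c(hist, d2_new)
    if (abs(d2 - d2_new) < tol * max(d2, .Machine$double.eps)) {
      converged <- TRUE
      d2 <- d2_new
      break
    }
    d2 <- d2_new
  }
  structure(list(lambda = setNames(lambda, ids),
                 projection = structure(proj$proj,
                                        dimnames = list(ids, colnames(points))),
                 curve = curve, dist_history = hist, converged = converged),
            class = "PseudoOrderResult")
}

# spline-smooth each coordinate against lambda; returns an ordered polyline
.smooth_curve <- function(points, lambda, df = 5) {
  ord <- order(lambda)
  lam <- lambda[ord]
  sapply(1:2, function(k) {
    y <- points[ord, k]
    if (length(unique(lam)) < 4 || sd(y) == 0) return(y)
    fit <- tryCatch({
      if (is.null(df)) smooth.spline(lam, y)
      else smooth.spline(lam, y, df = min(df, length(unique(lam)) - 1))
    }, error = function(e) NULL)
    if (is.null(fit)) y else predict(fit, lam)$y
  })
}

# project points onto a polyline; lambda = arc length of the projection
.project_polyline <- function(points, curve) {
  n_seg <- nrow(curve) - 1
  seg <- curve[-1, , drop = FALSE] - curve[-nrow(curve), , drop = FALSE]
  seg_len2 <- rowSums(seg^2)
  cum_len <- c(0, cumsum(sqrt(seg_len2)))
  n <- nrow(points)
  proj <- matrix(NA_real_, n, 2)
  lambda <- numeric(n)
  dist2 <- numeric(n)
  for (i in seq_len(n)) {
    dp <- sweep(curve[-nrow(curve), , drop = FALSE], 2, points[i, ], "-")
    tt <- pmin(1, pmax(0, -rowSums(dp * seg) / pmax(seg_len2, .Machine$double.eps)))
    cand <- curve[-nrow(curve), , drop = FALSE] + seg * tt
    d2 <- rowSums(sweep(cand, 2, points[i, ], "-")^2)
    j <- which.min(d2)
    proj[i, ] <- cand[j, ]
    lambda[i] <- cum_len[j] + tt[j] * sqrt(seg_len2[j])
    dist2[i] <- d2[j]
  }
  list(proj = proj, lambda = lambda, dist2 = dist2)
}

#' Orient a pseudo-order so an anchor population starts it
#'
#' Lambda is negated (and shifted back to start at its minimum) when the mean
#' lambda of the anchor cells exceeds the mean lambda of the remaining cells;
#' developmental direction is thereby fixed by, e.g., the earliest sampling
#' stage. Idempotent.
#'
#' @param result a `PseudoOrderResult`.
#' @param anchor_cells identifiers of the anchor (earliest) cells.
#' @return the result with `lambda` possibly reversed.
#' @export
orient_pseudoorder <- function(result, anchor_cells) {
  lam <- result$lambda
  anchor_cells <- intersect(anchor_cells, names(lam))
  stopifnot(length(anchor_cells) >= 1)
  rest <- setdiff(names(lam), anchor_cells)
  if (length(rest) && mean(lam[anchor_cells]) > mean(lam[rest])) {
    lam <- -lam
    lam <- lam - min(lam)
    result$lambda <- lam
    result$curve <- result$curve[rev(seq_len(nrow(result$curve))), , drop = FALSE]
  }
  result
}

#' Smoothed expression dynamics of pattern genes along a pseudo-order
#'
#' Builds the visualization-ready matrix: rows are pattern genes ordered first
#' by category and then by ascending plexus-comparison p value; columns are
#' cells ordered by lambda; each row is smoothed over adjacent cells with
#' [smooth_over_cells()]. Genes absent from the dataset are dropped with a
#' warning.
#'
#' @param dataset a normalized [expression_dataset()].
#' @param order a `PseudoOrderResult` (or a named lambda vector).
#' @param pattern_table output of [pattern_genes()] (rows with category
#'   `other` are ignored).
#' @param window smoothing window in cells (default 20).
#' @return list: `matrix` (genes x cells, smoothed, columns in pseudo-order)
#'   and `gene_order`.
#' @export
pattern_dynamics <- function(dataset, order, pattern_table, window = 20) {
  lam <- if (inherits(order, "PseudoOrderResult")) order$lambda else order
  cells <- names(sort(lam))
  tab <- pattern_table[pattern_table$category != "other", , drop = FALSE]
  missing <- setdiff(tab$gene, rownames(dataset$norm))
  if (length(missing)) {
    warning(length(missing), " pattern gene(s) absent from the dataset, dropped")
    tab <- tab[!tab$gene %in% missing, , drop = FALSE]
  }
  tab <- tab[order(tab$category, tab$p_plexus), , drop = FALSE]
  m <- as.matrix(dataset$norm[tab$gene, cells, drop = FALSE])
  sm <- t(apply(m, 1, smooth_over_cells, window = window))
  dimnames(sm) <- list(tab$gene, cells)
  list(matrix = sm, gene_order = tab$gene)
}
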