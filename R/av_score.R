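#' Min-max scale a vector to the 0-10 range
#'
#' `(x - min) / (max - min) * 10`, computed across all cells. A constant
#' vector maps to all zeros, so a gene with no variation biases neither the
#' arterial nor the venous side.
#'
#' @param values numeric vector (finite).
#' @return numeric vector in `[0, 10]`.
#' @export
scale_gene_0_10 <- function(values) {
  stopifnot(all(is.finite(values)))
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1]) * 10
}

#' Per-cell arterial and venous feature scores
#'
#' Three steps, each across all cells of the dataset: (i) min-max scale each
#' marker gene's normalized expression to 0-10; (ii) per cell, average the
#' scaled values of the arterial markers and of the venous markers; (iii)
#' rescale each of the two averaged vectors to 0-10. The result is one
#' arterial score `S_a` and one venous score `S_v` per cell, both in
#' `[0, 10]`, with the extremes attained by construction.
#'
#' Because every step is invariant to per-gene positive affine transforms of
#' the expression values, the scores (and hence identity calls) do not depend
#' on the logarithm base used during normalization.
#'
#' @param dataset a normalized [expression_dataset()] with at least 2 cells.
#' @param signatures a [signature_set()]; marker symbols absent from the
#'   dataset are dropped with a warning, but each side must retain at least
#'   one gene.
#' @return data.frame of class `AVScoreTable` with columns `cell`, `S_a`,
#'   `S_v`.
#' @export
av_scores <- function(dataset, signatures = signature_set()) {
  stopifnot(!is.null(dataset$norm), ncol(dataset$norm) >= 2)
  side_score <- function(genes, side) {
    present <- intersect(genes, rownames(dataset$norm))
    if (!length(present))
      stop("no ", side, " signature gene found in the dataset")
    if (length(present) < length(genes))
      warning(length(genes) - length(present), " ", side,
              " signature gene(s) absent and dropped; ", length(present),
              " used")
    scaled <- t(apply(as.matrix(dataset$norm[present, , drop = FALSE]), 1,
                      scale_gene_0_10))
    if (length(present) == 1) scaled <- matrix(scaled, nrow = 1)
    scale_gene_0_10(colMeans(scaled))
  }
  out <- data.frame(cell = colnames(dataset$norm),
                    S_a = side_score(signatures$arterial, "arterial"),
                    S_v = side_score(signatures$venous, "venous"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("AVScoreTable", "data.frame")
  out
}

#' Classify arteriovenous identity from feature scores
#'
#' A cell is `arterial` iff `S_a > tau` and `S_v <= tau`, `venous` iff
#' `S_v > tau` and `S_a <= tau`, `double` iff both exceed `tau`, and
#' `neither` otherwise (ties at the threshold are `neither`).
#'
#' @param table an `AVScoreTable` from [av_scores()].
#' @param tau identity threshold on the 0-10 score scale (default 5).
#' @return factor over cells with levels arterial, venous, double, neither.
#' @export
classify_av <- function(table, tau = 5) {
  a <- table$S_a > tau
  v <- table$S_v > tau
  id <- ifelse(a & v, "double",
               ifelse(a, "arterial", ifelse(v, "venous", "neither")))
  factor(setNames(id, table$cell),
         levels = c("arterial", "venous", "double", "neither"))
}

#' Per-cluster mean scores and confidence ellipses
#'
#' For each cluster, the sample mean and covariance of `(S_a, S_v)` define a
#' coverage ellipse `{x : (x - mu)' Sigma^-1 (x - mu) <= q}` with `q` the
#' chi-square quantile at `coverage` with 2 degrees of freedom (for
#' `coverage = 0.5`, `q = -2 log(0.5)`). Clusters with fewer than 3 cells or
#' a singular covariance are flagged degenerate rather than erroring.
#'
#' @param table an `AVScoreTable`.
#' @param labels cluster label per cell (same order as `table`).
#' @param coverage ellipse coverage probability (default 0.5).
#' @return data.frame, one row per cluster: mean scores, covariance entries,
#'   ellipse semi-axes `r1 >= r2`, orientation angle (radians), `q`,
#'   `degenerate` flag.
#' @export
cluster_ellipse <- function(table, labels, coverage = 0.5) {
  stopifnot(length(labels) == nrow(table), coverage > 0, coverage < 1)
  q <- qchisq(coverage, df = 2)
  res <- lapply(split(seq_len(nrow(table)), labels), function(idx) {
    xy <- cbind(table$S_a[idx], table$S_v[idx])
    mu <- colMeans(xy)
    row <- data.frame(n = length(idx), mean_Sa = mu[1], mean_Sv = mu[2],
                      cov_aa = NA_real_, cov_av = NA_real_, cov_vv = NA_real_,
                      r1 = NA_real_, r2 = NA_real_, angle = NA_real_,
                      q = q, degenerate = TRUE)
    if (length(idx) >= 3) {
      S <- cov(xy)
      row[c("cov_aa", "cov_av", "cov_vv")] <- c(S[1, 1], S[1, 2], S[2, 2])
      ev <- eigen(S, symmetric = TRUE)
      if (min(ev$values) > max(ev$values) * 1e-10 && min(ev$values) > 0) {
        row$r1 <- sqrt(ev$values[1] * q)
        row$r2 <- sqrt(ev$values[2] * q)
        row$angle <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
        row$degenerate <- FALSE
      }
    }
    row
  })
  out <- do.call(rbind, res)
  out <- cbind(cluster = names(res), out)
  rownames(out) <- NULL
  out
}

#' Test whether 2D points fall inside a coverage ellipse
#'
#' @param points two-column matrix of (S_a, S_v) points.
#' @param ellipse one row of the [cluster_ellipse()] output.
#' @return logical vector; `(x-mu)' Sigma^-1 (x-mu) <= q`.
#' @export
in_ellipse <- function(points, ellipse) {
  stopifnot(!ellipse$degenerate)
  S <- matrix(c(ellipse$cov_aa, ellipse$cov_av, ellipse$cov_av, ellipse$cov_vv), 2)
  mu <- c(ellipse$mean_Sa, ellipse$mean_Sv)
  d <- sweep(as.matrix(points), 2, mu)
  md <- rowSums((d %*% solve(S)) * d)
  md <= ellipse$q
}
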