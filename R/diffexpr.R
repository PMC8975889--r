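#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' For every gene detected (normalized value > 0) in at least `min_pct` of the
#' cells of either group, a two-sided two-sample Wilcoxon rank-sum test is run
#' on the normalized values, using the normal approximation with mid-ranks and
#' the tie variance correction (no continuity correction). P values are
#' BH-adjusted across the tested genes. A gene is flagged `retained` when its
#' linear fold change (in either direction) is at least `fc_min` and its
#' adjusted p value is at most `alpha`.
#'
#' The linear fold change is computed on the de-logged scale as
#' `(mean(expm1(norm)) + eps) / (mean(expm1(norm)) + eps)` between the two
#' groups (`eps = 1e-9` guards against division by zero); `log_fc` reports the
#' difference of group means on the normalized (log) scale.
#'
#' @param dataset a normalized [expression_dataset()].
#' @param group1,group2 disjoint character vectors of cell identifiers.
#' @param min_pct minimum expressing fraction in either group (default 0.25).
#' @param fc_min linear fold-change threshold for retention (default 2).
#' @param alpha adjusted-p threshold for retention (default 0.05).
#' @return data.frame, one row per tested gene: `gene`, `log_fc`, `fc`
#'   (linear, group1 over group2), `p`, `p_adj`, `pct_1`, `pct_2`,
#'   `direction` (`up` = higher in group1), `retained`.
#' @export
wilcoxon_deg <- function(dataset, group1, group2, min_pct = 0.25,
                         fc_min = 2, alpha = 0.05) {
  stopifnot(!is.null(dataset$norm), length(group1) > 0, length(group2) > 0)
  if (length(intersect(group1, group2)))
    stop("groups overlap: ", paste(head(intersect(group1, group2), 5), collapse = ", "))
  miss <- setdiff(c(group1, group2), colnames(dataset$norm))
  if (length(miss)) stop("unknown cells: ", paste(head(miss, 5), collapse = ", "))

  x1 <- as.matrix(dataset$norm[, group1, drop = FALSE])
  x2 <- as.matrix(dataset$norm[, group2, drop = FALSE])
  pct1 <- rowMeans(x1 > 0)
  pct2 <- rowMeans(x2 > 0)
  test <- pct1 >= min_pct | pct2 >= min_pct
  if (!any(test))
    return(data.frame(gene = character(), log_fc = numeric(), fc = numeric(),
                      p = numeric(), p_adj = numeric(), pct_1 = numeric(),
                      pct_2 = numeric(), direction = character(),
                      retained = logical()))
  x1 <- x1[test, , drop = FALSE]
  x2 <- x2[test, , drop = FALSE]

  p <- rank_sum_p(x1, x2)
  eps <- 1e-9
  m1 <- rowMeans(expm1(x1))
  m2 <- rowMeans(expm1(x2))
  fc <- (m1 + eps) / (m2 + eps)
  log_fc <- rowMeans(x1) - rowMeans(x2)
  p_adj <- bh_adjust(p)
  out <- data.frame(gene = rownames(x1), log_fc = log_fc, fc = fc, p = p,
                    p_adj = p_adj, pct_1 = pct1[test], pct_2 = pct2[test],
                    direction = ifelse(log_fc >= 0, "up", "down"),
                    retained = pmax(fc, 1 / fc) >= fc_min & p_adj <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# vectorized two-sided Mann-Whitney p values with tie correction,
# normal approximation, no continuity correction; rows are genes
rank_sum_p <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2); n <- n1 + n2
  vapply(seq_len(nrow(x1)), function(i) {
    v <- c(x1[i, ], x2[i, ])
    r <- rank(v)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (u - n1 * n2 / 2) / sqrt(sigma2)
    2 * pnorm(-abs(z))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' returned in the input order. Input values outside `[0, 1]` are an error.
#'
#' @param pvals numeric vector of raw p values.
#' @return adjusted p values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Fisher's method for combining independent p values
#'
#' `X = -2 sum(log p_i)` referred to the upper tail of a chi-square
#' distribution with `2k` degrees of freedom. Zero p values are clamped to
#' the smallest positive double with a warning.
#'
#' @param pvals numeric vector of k >= 1 p values in (0, 1].
#' @return the combined p value.
#' @export
fisher_combine <- function(pvals) {
  stopifnot(length(pvals) >= 1, all(is.finite(pvals)), all(pvals <= 1))
  if (any(pvals <= 0)) {
    warning("p value(s) <= 0 clamped to the smallest positive double")
    pvals <- pmax(pvals, .Machine$double.xmin)
  }
  x <- -2 * sum(log(pvals))
  pchisq(x, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Moving-average smoothing along a cell ordering
#'
#' Centered moving average of width `window` applied to `values` arranged in
#' the order given by `order` (a permutation of cell indices); the window is
#' truncated at the series ends. The smoothed values are returned in the
#' original indexing.
#'
#' @param values numeric vector over cells.
#' @param order integer permutation of `seq_along(values)` (e.g. the ranking
#'   by pseudo-order lambda).
#' @param window window width in cells (default 20). For even widths the
#'   window covers `floor((window-1)/2)` cells before and
#'   `ceiling((window-1)/2)` after the focal cell.
#' @return numeric vector, original indexing.
#' @export
smooth_over_cells <- function(values, order = seq_along(values), window = 20) {
  if (window < 1) stop("window must be >= 1")
  stopifnot(length(order) == length(values),
            all(sort(order) == seq_along(values)))
  v <- values[order]
  n <- length(v)
  lo <- floor((window - 1) / 2)
  hi <- ceiling((window - 1) / 2)
  sm <- vapply(seq_len(n), function(i)
    mean(v[max(1, i - lo):min(n, i + hi)]), numeric(1))
  out <- numeric(n)
  out[order] <- sm
  out
}

#' Categorize arterial pattern genes across a three-stage continuum
#'
#' Genes up-regulated in the mid stage relative to the early stage are
#' arterial *segregation* genes (the settling of the first arterial fate);
#' genes up-regulated in the late stage relative to the mid stage are
#' arterial *strengthening* genes. Both contrasts use [wilcoxon_deg()] with
#' the given fold-change threshold. A gene passing both contrasts is assigned
#' to segregation (the earlier event) and flagged. When the two plexus
#' cluster labels are supplied, a per-gene raw Wilcoxon p value between them
#' is attached for downstream ordering of heatmap rows.
#'
#' @param dataset a normalized [expression_dataset()].
#' @param labels cluster label per cell (named by cell, or in dataset order).
#' @param early,mid,late the three stage labels (defaults EP1, EP2, EP3).
#' @param fc_min fold-change threshold (default 1.5).
#' @param plexus optional length-2 labels (e.g. `c("EP6", "EP7")`) whose
#'   per-gene comparison p value is attached as `p_plexus`.
#' @return data.frame: `gene`, `category` (`arterial_segregation`,
#'   `arterial_strengthening`, `other`), `both_stages`, `p_segregation`,
#'   `p_strengthening`, `p_plexus`.
#' @export
pattern_genes <- function(dataset, labels, early = "EP1", mid = "EP2",
                          late = "EP3", fc_min = 1.5, plexus = NULL) {
  labels <- .cell_labels(dataset, labels)
  for (lv in c(early, mid, late))
    if (!any(labels == lv)) stop("no cells labeled ", lv)
  cells_of <- function(lv) names(labels)[labels == lv]
  seg <- wilcoxon_deg(dataset, cells_of(mid), cells_of(early), fc_min = fc_min)
  str <- wilcoxon_deg(dataset, cells_of(late), cells_of(mid), fc_min = fc_min)
  seg_up <- seg$gene[seg$retained & seg$direction == "up"]
  str_up <- str$gene[str$retained & str$direction == "up"]
  all_genes <- union(seg$gene, str$gene)
  category <- ifelse(all_genes %in% seg_up, "arterial_segregation",
                     ifelse(all_genes %in% str_up, "arterial_strengthening",
                            "other"))
  out <- data.frame(
    gene = all_genes, category = category,
    both_stages = all_genes %in% intersect(seg_up, str_up),
    p_segregation = seg$p[match(all_genes, seg$gene)],
    p_strengthening = str$p[match(all_genes, str$gene)],
    p_plexus = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(plexus)) {
    stopifnot(length(plexus) == 2)
    g1 <- cells_of(plexus[1]); g2 <- cells_of(plexus[2])
    if (length(g1) && length(g2)) {
      px <- wilcoxon_deg(dataset, g1, g2, min_pct = 0, fc_min = 1, alpha = 1)
      out$p_plexus <- px$p[match(out$gene, px$gene)]
    }
  }
  out
}

# resolve a label vector to a named factor over dataset cells
.cell_labels <- function(dataset, labels) {
  ids <- colnames(dataset$counts)
  if (is.null(names(labels))) {
    stopifnot(length(labels) == length(ids))
    names(labels) <- ids
  }
  labels[ids]
}
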