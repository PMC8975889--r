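#' Cell-cycle phase scores and assignments
#'
#' Module-score construction with expression-matched background control: all
#' genes are binned into `n_bins` bins of equal size by their mean normalized
#' expression across cells; for each signature gene, `ctrl_size` control genes
#' are sampled (with replacement if the bin is small) from the same bin; the
#' phase score of a cell is the mean expression of the signature genes minus
#' the mean expression of the pooled control genes. A cell whose G1/S and
#' G2/M scores are both `<= 0` is called `G1`; otherwise the phase of the
#' larger score wins (`S` for the G1/S score, `G2M` for the G2/M score).
#'
#' @param dataset a normalized [expression_dataset()].
#' @param signatures a [signature_set()] with non-empty `g1s` and `g2m` after
#'   intersection with the dataset's genes.
#' @param n_bins number of mean-expression bins for control matching.
#' @param ctrl_size control genes drawn per signature gene.
#' @param seed RNG seed for control sampling (restored on exit).
#' @return data.frame with columns `cell`, `g1s_score`, `g2m_score`, `phase`.
#' @export
cell_cycle_scores <- function(dataset, signatures = signature_set(),
                              n_bins = 25, ctrl_size = 50, seed = 42) {
  stopifnot(!is.null(dataset$norm))
  norm <- dataset$norm
  all_genes <- rownames(norm)
  g1s <- intersect(signatures$g1s, all_genes)
  g2m <- intersect(signatures$g2m, all_genes)
  if (!length(g1s)) stop("no G1/S signature gene found in the dataset")
  if (!length(g2m)) stop("no G2/M signature gene found in the dataset")

  gene_means <- rowMeans(norm)
  # equal-occupancy bins on ranked mean expression
  bins <- cut(rank(gene_means, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- all_genes
  by_bin <- split(all_genes, bins)

  # evaluate both sets under one seeded RNG stream
  scores <- withr_seed(seed, function() {
    f <- function(set) {
      ctrl <- unlist(lapply(set, function(g) {
        pool <- by_bin[[as.character(bins[g])]]
        sample(pool, ctrl_size, replace = length(pool) < ctrl_size)
      }))
      colMeans(norm[set, , drop = FALSE]) -
        colMeans(norm[unique(ctrl), , drop = FALSE])
    }
    list(g1s = f(g1s), g2m = f(g2m))
  })

  phase <- ifelse(scores$g1s <= 0 & scores$g2m <= 0, "G1",
                  ifelse(scores$g1s > scores$g2m, "S", "G2M"))
  data.frame(cell = colnames(norm),
             g1s_score = as.numeric(scores$g1s),
             g2m_score = as.numeric(scores$g2m),
             phase = factor(phase, levels = c("G1", "S", "G2M")),
             stringsAsFactors = FALSE, row.names = NULL)
}

# run f() under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}
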