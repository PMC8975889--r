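#' Map gene symbols through a homolog table
#'
#' One-to-one rows map directly; one-to-many relations are resolved per
#' `policy` (`"keep_all"` returns every target and flags the gene as
#' ambiguous, `"first"` keeps the first listed target). Unmapped genes are
#' dropped and their count reported via a message.
#'
#' @param genes_in character vector of species-A symbols.
#' @param map data.frame with columns symbol_a, symbol_b (see
#'   [read_homolog_map()]).
#' @param policy `"keep_all"` or `"first"`.
#' @return data.frame: `input`, `target`, `ambiguous`.
#' @export
map_homologs <- function(genes_in, map, policy = c("keep_all", "first")) {
  policy <- match.arg(policy)
  if (!nrow(map)) stop("empty homolog map")
  hits <- map[map$symbol_a %in% genes_in, , drop = FALSE]
  n_unmapped <- sum(!genes_in %in% map$symbol_a)
  if (n_unmapped) message(n_unmapped, " gene(s) had no homolog and were dropped")
  if (!nrow(hits))
    return(data.frame(input = character(), target = character(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  n_targets <- table(hits$symbol_a)
  if (policy == "first")
    hits <- hits[!duplicated(hits$symbol_a), , drop = FALSE]
  data.frame(input = hits$symbol_a, target = hits$symbol_b,
             ambiguous = as.logical(n_targets[hits$symbol_a] > 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Conserved cluster markers shared between two species
#'
#' A gene is a conserved marker when it is a retained DEG in species A and at
#' least one of its homologs is a retained DEG with the same direction in
#' species B. Records are ranked by Fisher's combined probability of the two
#' raw p values ([fisher_combine()]).
#'
#' @param deg_a,deg_b [wilcoxon_deg()] tables for the matched cluster
#'   contrast in species A and species B.
#' @param map homolog map (species A symbols in `symbol_a`).
#' @return data.frame of class `ConservedGeneTable`, ascending `combined_p`:
#'   gene (species-A symbol), homolog, direction, p_a, p_b, fc_a, fc_b,
#'   combined_p, n_comparisons, ambiguous.
#' @export
conserved_cluster_markers <- function(deg_a, deg_b, map) {
  a <- deg_a[deg_a$retained, , drop = FALSE]
  b <- deg_b[deg_b$retained, , drop = FALSE]
  mapped <- map_homologs(a$gene, map)
  recs <- list()
  for (i in seq_len(nrow(mapped))) {
    g <- mapped$input[i]; h <- mapped$target[i]
    ia <- match(g, a$gene)
    ib <- match(h, b$gene)
    if (is.na(ib) || a$direction[ia] != b$direction[ib]) next
    recs[[length(recs) + 1]] <- data.frame(
      gene = g, homolog = h, direction = a$direction[ia],
      p_a = a$p[ia], p_b = b$p[ib], fc_a = a$fc[ia], fc_b = b$fc[ib],
      combined_p = fisher_combine(c(a$p[ia], b$p[ib])),
      n_comparisons = 2L, ambiguous = mapped$ambiguous[i],
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(), homolog = character(),
               direction = character(), p_a = numeric(), p_b = numeric(),
               fc_a = numeric(), fc_b = numeric(), combined_p = numeric(),
               n_comparisons = integer(), ambiguous = logical(),
               stringsAsFactors = FALSE)
  out <- out[order(out$combined_p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ConservedGeneTable", "data.frame")
  out
}

#' Conserved arterial genes across four arterial-vs-venous comparisons
#'
#' A conserved arterial gene must be a retained, up-regulated DEG in all four
#' comparisons: each of the two arterial populations versus the venous
#' population, in both species. The first two tables are the reference
#' species (whose symbols are reported); the last two are the other species,
#' linked through the homolog map. Records are ranked by Fisher's combined
#' probability of the four raw p values (chi-square with 8 df).
#'
#' @param deg_sets list of exactly 4 [wilcoxon_deg()] tables:
#'   `list(refAEC1, refAEC2, otherAEC1, otherAEC2)`.
#' @param map homolog map with the reference species in `symbol_a`.
#' @return `ConservedGeneTable` with per-comparison p values and combined_p.
#' @export
conserved_arterial_genes <- function(deg_sets, map) {
  if (length(deg_sets) != 4) stop("exactly four DEG tables required")
  up <- lapply(deg_sets, function(d) d[d$retained & d$direction == "up", ,
                                       drop = FALSE])
  candidates <- intersect(up[[1]]$gene, up[[2]]$gene)
  mapped <- map_homologs(candidates, map)
  recs <- list()
  for (i in seq_len(nrow(mapped))) {
    g <- mapped$input[i]; h <- mapped$target[i]
    i3 <- match(h, up[[3]]$gene)
    i4 <- match(h, up[[4]]$gene)
    if (is.na(i3) || is.na(i4)) next
    ps <- c(up[[1]]$p[match(g, up[[1]]$gene)],
            up[[2]]$p[match(g, up[[2]]$gene)],
            up[[3]]$p[i3], up[[4]]$p[i4])
    recs[[length(recs) + 1]] <- data.frame(
      gene = g, homolog = h, p_1 = ps[1], p_2 = ps[2], p_3 = ps[3],
      p_4 = ps[4], combined_p = fisher_combine(ps), n_comparisons = 4L,
      ambiguous = mapped$ambiguous[i], stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(), homolog = character(), p_1 = numeric(),
               p_2 = numeric(), p_3 = numeric(), p_4 = numeric(),
               combined_p = numeric(), n_comparisons = integer(),
               ambiguous = logical(), stringsAsFactors = FALSE)
  # a gene with several homologs may satisfy the screen through more than one;
  # keep the best-supported record per reference gene
  out <- out[order(out$combined_p), , drop = FALSE]
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ConservedGeneTable", "data.frame")
  out
}

#' k-nearest-neighbour label transfer in a shared embedding
#'
#' Each query point receives the majority label among its `k` nearest
#' reference points (Euclidean distance); ties are broken in favour of the
#' tied label with the smallest summed distance. The vote fraction (winning
#' votes / k) is reported as a confidence measure.
#'
#' @param reference_embedding numeric matrix (reference cells x dims).
#' @param reference_labels factor/character labels over reference rows.
#' @param query_embedding numeric matrix (query cells x same dims).
#' @param k neighbourhood size (default 15); must not exceed the reference
#'   size.
#' @return data.frame: `cell` (query rownames or indices), `label`,
#'   `vote_frac`.
#' @export
knn_transfer <- function(reference_embedding, reference_labels,
                         query_embedding, k = 15) {
  ref <- as.matrix(reference_embedding)
  qry <- as.matrix(query_embedding)
  stopifnot(ncol(ref) == ncol(qry), k >= 1)
  if (k > nrow(ref)) stop("k exceeds the reference size")
  labs <- as.character(reference_labels)
  stopifnot(length(labs) == nrow(ref))
  ids <- rownames(qry)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(qry)))
  ref_sq <- rowSums(ref^2)
  out <- lapply(seq_len(nrow(qry)), function(i) {
    d2 <- ref_sq - 2 * as.numeric(ref %*% qry[i, ]) + sum(qry[i, ]^2)
    nn <- order(d2)[seq_len(k)]
    votes <- table(labs[nn])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) > 1) {
      sums <- vapply(winners, function(w)
        sum(sqrt(pmax(d2[nn][labs[nn] == w], 0))), numeric(1))
      winners <- winners[which.min(sums)]
    }
    data.frame(cell = ids[i], label = winners[1],
               vote_frac = as.numeric(max(votes)) / k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
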