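#' Data-derived expression threshold for interaction calling
#'
#' The upper quartile (75th percentile, linear interpolation between order
#' statistics) of expression values pooled over all genes of all supplied
#' datasets. By default the statistic is computed over per-gene mean
#' normalized expression; per-entry and nonzero-entry conventions are
#' available. The published analysis of this kind yielded 1.34 on its own
#' data, which can be supplied directly to [detect_interactions()] to
#' reproduce that setting.
#'
#' @param datasets a normalized [expression_dataset()] or list of them.
#' @param method population over which the quartile is taken: `"gene_mean"`
#'   (default), `"entry"` (every matrix entry), `"nonzero_entry"`.
#' @return the threshold (>= 0).
#' @export
expression_threshold <- function(datasets,
                                 method = c("gene_mean", "entry",
                                            "nonzero_entry")) {
  method <- match.arg(method)
  if (inherits(datasets, "ExpressionDataset")) datasets <- list(datasets)
  if (!length(datasets)) stop("no datasets supplied")
  vals <- unlist(lapply(datasets, function(d) {
    stopifnot(!is.null(d$norm))
    switch(method,
           gene_mean = as.numeric(rowMeans(d$norm)),
           entry = as.numeric(as.matrix(d$norm)),
           nonzero_entry = d$norm@x)
  }))
  if (!length(vals)) return(0)
  as.numeric(quantile(vals, 0.75, type = 7))
}

.expressing_fraction <- function(dataset, gene, threshold) {
  if (!gene %in% rownames(dataset$norm)) return(0)
  mean(dataset$norm[gene, ] > threshold)
}

#' Call heterologous ligand-receptor interactions between two populations
#'
#' For every (ligand, receptor) pair and both directions, an interaction is
#' called iff the ligand's normalized expression exceeds `threshold` in
#' strictly more than `min_frac` of the sender population's cells AND the
#' receptor's exceeds it in strictly more than `min_frac` of the receiver
#' population's cells. Genes absent from a dataset count as never expressed.
#'
#' @param vec_data,mc_data normalized [expression_dataset()]s for the VEC and
#'   mural-cell populations.
#' @param pairs data.frame with columns ligand, receptor (see
#'   [read_lr_pairs()]).
#' @param threshold expression cutoff; see [expression_threshold()].
#' @param min_frac expressing-fraction cutoff (default 0.5, strict).
#' @param pair_id optional label stored with each call.
#' @return data.frame of calls: ligand, receptor, direction (`MC->VEC` when
#'   the mural cells send the ligand), ligand_frac, receptor_frac,
#'   threshold_used, dataset_pair_id.
#' @export
detect_interactions <- function(vec_data, mc_data, pairs, threshold,
                                min_frac = 0.5, pair_id = NA_character_) {
  stopifnot(threshold >= 0, !is.null(vec_data$norm), !is.null(mc_data$norm))
  pairs <- unique(pairs[, c("ligand", "receptor")])
  calls <- list()
  for (i in seq_len(nrow(pairs))) {
    lg <- pairs$ligand[i]; rc <- pairs$receptor[i]
    # MC sends ligand, VEC receives
    lf <- .expressing_fraction(mc_data, lg, threshold)
    rf <- .expressing_fraction(vec_data, rc, threshold)
    if (lf > min_frac && rf > min_frac)
      calls[[length(calls) + 1]] <- data.frame(
        ligand = lg, receptor = rc, direction = "MC->VEC",
        ligand_frac = lf, receptor_frac = rf,
        threshold_used = threshold, dataset_pair_id = pair_id,
        stringsAsFactors = FALSE)
    # VEC sends ligand, MC receives
    lf2 <- .expressing_fraction(vec_data, lg, threshold)
    rf2 <- .expressing_fraction(mc_data, rc, threshold)
    if (lf2 > min_frac && rf2 > min_frac)
      calls[[length(calls) + 1]] <- data.frame(
        ligand = lg, receptor = rc, direction = "VEC->MC",
        ligand_frac = lf2, receptor_frac = rf2,
        threshold_used = threshold, dataset_pair_id = pair_id,
        stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(ligand = character(), receptor = character(),
                      direction = character(), ligand_frac = numeric(),
                      receptor_frac = numeric(), threshold_used = numeric(),
                      dataset_pair_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, calls)
}

#' Venn partition of interaction call sets
#'
#' Assigns every called pair to exactly one region of the Venn partition of
#' the named call sets (e.g. the three mural-cell/VEC dataset pairs) and
#' counts each region. Region names are `+`-joined member names.
#'
#' @param call_sets named list (>= 2) of character vectors of pair
#'   identifiers, e.g. `"Ligand|Receptor|direction"`.
#' @return data.frame: region, n, members (comma-joined identifiers).
#' @export
shared_distinct <- function(call_sets) {
  stopifnot(length(call_sets) >= 2, !is.null(names(call_sets)))
  universe <- unique(unlist(call_sets))
  if (!length(universe))
    return(data.frame(region = character(), n = integer(),
                      members = character(), stringsAsFactors = FALSE))
  membership <- sapply(call_sets, function(s) universe %in% s)
  if (is.null(dim(membership))) membership <- matrix(membership, nrow = 1)
  region <- apply(membership, 1, function(m)
    paste(names(call_sets)[m], collapse = "+"))
  agg <- split(universe, region)
  data.frame(region = names(agg),
             n = lengths(agg),
             members = vapply(agg, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Directional bipartite networks of shared interaction calls
#'
#' Splits calls by direction into two edge lists (mural-cell ligand to VEC
#' receptor, and the reverse), deduplicates nodes and attaches node degrees.
#'
#' @param calls a data.frame of calls from [detect_interactions()].
#' @return list with one element per direction, each holding `edges`
#'   (ligand, receptor) and `degree` (named counts over nodes).
#' @export
interaction_network <- function(calls) {
  out <- lapply(split(calls, calls$direction), function(d) {
    edges <- unique(d[, c("ligand", "receptor")])
    deg <- table(c(paste0("L:", edges$ligand), paste0("R:", edges$receptor)))
    list(edges = edges, degree = deg)
  })
  out
}
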