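#' Specification of a synthetic VEC-like dataset
#'
#' Describes the generative model used by all synthetic-data generators:
#' negative-binomial UMI counts (gamma-Poisson mixture) around a log-normal
#' per-gene baseline, per-cluster marker programs expressed as log2
#' fold-changes, optional continuous latent time acting through per-gene
#' logistic ramps, optional cell-cycle structure, multiplicative log-normal
#' library-size variation, mild per-batch gene effects, and deliberate label
#' flips for testing refinement.
#'
#' @param n_genes,n_cells dataset dimensions.
#' @param cluster_profile list of clusters, each a list with `name`,
#'   `fraction` (fractions must sum to 1 within 1e-9), optional `program`
#'   (named numeric vector of log2 fold-changes over baseline; must be
#'   finite) and optional `identity` (`"arterial"`, `"venous"`, `"neither"`).
#' @param latent_time_clusters cluster names carrying a continuous latent
#'   order (uniform on 0-1).
#' @param time_genes named numeric vector: per-gene log2-amplitude of the
#'   logistic latent-time ramp (random midpoints in 0.25-0.75).
#' @param marker_sets named gene lists (arterial, venous, g1s, g2m, ...);
#'   named genes are guaranteed to exist in the gene universe and are given a
#'   moderately expressed baseline so signatures are detectable.
#' @param library_size_mean expected UMIs per cell.
#' @param marker_base_count expected baseline (off-state) UMI count of named
#'   program/marker genes; programs act multiplicatively on top of it.
#' @param dispersion negative-binomial overdispersion (> 0; NB size =
#'   1/dispersion).
#' @param lib_sdlog sdlog of the log-normal library-size factors.
#' @param baseline_sdlog sdlog of the log-normal baseline gene abundances.
#' @param batch_count number of batches (>= 1).
#' @param batch_sdlog sd (log2) of per-batch gene effects for batches > 1.
#' @param cycle_fraction fraction of cells placed in S or G2M phase (split
#'   evenly) when g1s/g2m marker sets are supplied; 0 disables cycling.
#' @param cycle_lfc log2 boost of phase genes in cells of that phase.
#' @param flip_fraction fraction of cells whose *observed* cluster label is
#'   deliberately flipped to another cluster.
#' @param seed integer RNG seed; identical spec + seed gives identical output.
#' @return list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_genes, n_cells, cluster_profile,
                           latent_time_clusters = character(),
                           time_genes = numeric(),
                           marker_sets = list(),
                           library_size_mean = 1e5,
                           marker_base_count = 2,
                           dispersion = 0.2,
                           lib_sdlog = 0.3,
                           baseline_sdlog = 1.5,
                           batch_count = 1,
                           batch_sdlog = 0.1,
                           cycle_fraction = 0,
                           cycle_lfc = 1,
                           flip_fraction = 0,
                           seed = 1) {
  if (n_genes < 1) stop("invalid spec: n_genes must be >= 1")
  if (n_cells < 1) stop("invalid spec: n_cells must be >= 1")
  fr <- vapply(cluster_profile, function(cl) cl$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9)
    stop("invalid spec: cluster_profile fractions sum to ", sum(fr), ", not 1")
  if (any(fr <= 0)) stop("invalid spec: cluster_profile fraction <= 0")
  for (cl in cluster_profile) {
    if (is.null(cl$name)) stop("invalid spec: cluster_profile entry lacks a name")
    if (!is.null(cl$program) && any(!is.finite(cl$program)))
      stop("invalid spec: non-finite fold change in program of ", cl$name)
  }
  if (!is.finite(dispersion) || dispersion <= 0)
    stop("invalid spec: dispersion must be > 0")
  if (flip_fraction < 0 || flip_fraction >= 1)
    stop("invalid spec: flip_fraction must lie in [0, 1)")
  if (batch_count < 1) stop("invalid spec: batch_count must be >= 1")
  if (length(time_genes) && any(!is.finite(time_genes)))
    stop("invalid spec: non-finite fold change in time_genes")
  missing_lat <- setdiff(latent_time_clusters,
                         vapply(cluster_profile, `[[`, character(1), "name"))
  if (length(missing_lat))
    stop("invalid spec: latent_time_clusters not in cluster_profile: ",
         paste(missing_lat, collapse = ", "))
  structure(list(n_genes = n_genes, n_cells = n_cells,
                 cluster_profile = cluster_profile,
                 latent_time_clusters = latent_time_clusters,
                 time_genes = time_genes, marker_sets = marker_sets,
                 library_size_mean = library_size_mean,
                 marker_base_count = marker_base_count,
                 dispersion = dispersion, lib_sdlog = lib_sdlog,
                 baseline_sdlog = baseline_sdlog, batch_count = batch_count,
                 batch_sdlog = batch_sdlog, cycle_fraction = cycle_fraction,
                 cycle_lfc = cycle_lfc, flip_fraction = flip_fraction,
                 seed = seed),
            class = "SyntheticSpec")
}

.named_genes <- function(spec) {
  unique(c(unlist(lapply(spec$cluster_profile, function(cl) names(cl$program))),
           names(spec$time_genes), unlist(spec$marker_sets,
                                          use.names = FALSE)))
}

.gene_universe <- function(spec) {
  named <- .named_genes(spec)
  if (length(named) > spec$n_genes)
    stop("invalid spec: more named genes (", length(named),
         ") than n_genes (", spec$n_genes, ")")
  c(named, sprintf("gene_%05d", seq_len(spec$n_genes - length(named))))
}

.cluster_sizes <- function(spec) {
  fr <- vapply(spec$cluster_profile, `[[`, numeric(1), "fraction")
  sizes <- floor(fr * spec$n_cells)
  rem <- spec$n_cells - sum(sizes)
  if (rem > 0) {
    extra <- order(fr * spec$n_cells - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  if (any(sizes == 0)) stop("invalid spec: a cluster received 0 cells")
  setNames(sizes, vapply(spec$cluster_profile, `[[`, character(1), "name"))
}

#' Generate a synthetic VEC dataset with ground truth
#'
#' Samples a gene x cell UMI count matrix from the negative-binomial model of
#' [synthetic_spec()]: per-cell expected counts are the normalized product of
#' the baseline abundances and all planted log2 effects (cluster program,
#' latent-time ramp, cell-cycle phase, batch), scaled to a log-normal library
#' size. The returned dataset carries the *observed* cluster labels (with
#' deliberate flips, if requested) in `cell_meta`; the ground truth carries
#' the true labels and every planted quantity. The dataset comes normalized
#' (well platform).
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (class `GroundTruth`: per-cell table, per-cluster DE gene lists,
#'   time genes, the spec).
#' @export
generate_vec_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withr_seed(spec$seed, function() {
    genes <- .gene_universe(spec)
    G <- spec$n_genes
    sizes <- .cluster_sizes(spec)
    n <- spec$n_cells
    cl_names <- names(sizes)
    true_cluster <- rep(cl_names, sizes)
    cells <- sprintf("cell_%05d", seq_len(n))

    baseline <- rlnorm(G, meanlog = 0, sdlog = spec$baseline_sdlog)
    names(baseline) <- genes
    named <- .named_genes(spec)
    if (length(named)) {
      # named program/marker genes: baseline weight chosen so their expected
      # off-state count is marker_base_count (markers are near-silent outside
      # their compartment), with mild gene-to-gene jitter
      s_unnamed <- sum(baseline[setdiff(genes, named)])
      w <- spec$marker_base_count * s_unnamed /
        max(spec$library_size_mean - spec$marker_base_count * length(named), 1)
      baseline[named] <- w * rlnorm(length(named), meanlog = 0, sdlog = 0.2)
    }

    lfc <- matrix(0, nrow = G, ncol = n, dimnames = list(genes, cells))
    for (cl in spec$cluster_profile) {
      if (is.null(cl$program) || !length(cl$program)) next
      idx <- which(true_cluster == cl$name)
      lfc[names(cl$program), idx] <- lfc[names(cl$program), idx] + cl$program
    }

    latent_time <- rep(NA_real_, n)
    in_latent <- true_cluster %in% spec$latent_time_clusters
    if (any(in_latent) && length(spec$time_genes)) {
      latent_time[in_latent] <- runif(sum(in_latent))
      mids <- runif(length(spec$time_genes), 0.25, 0.75)
      tg <- names(spec$time_genes)
      ramp <- outer(seq_along(tg), which(in_latent),
                    function(gi, ci)
                      spec$time_genes[gi] *
                        stats::plogis((latent_time[ci] - mids[gi]) / 0.1))
      lfc[tg, in_latent] <- lfc[tg, in_latent] + ramp
    }

    phase <- rep("G1", n)
    if (spec$cycle_fraction > 0 &&
        all(c("g1s", "g2m") %in% names(spec$marker_sets))) {
      phase <- sample(c("G1", "S", "G2M"), n, replace = TRUE,
                      prob = c(1 - spec$cycle_fraction,
                               spec$cycle_fraction / 2,
                               spec$cycle_fraction / 2))
      g1s <- spec$marker_sets$g1s
      g2m <- spec$marker_sets$g2m
      lfc[g1s, phase == "S"] <- lfc[g1s, phase == "S"] + spec$cycle_lfc
      lfc[g2m, phase == "G2M"] <- lfc[g2m, phase == "G2M"] + spec$cycle_lfc
    }

    batch <- rep_len(paste0("batch", seq_len(spec$batch_count)), n)
    if (spec$batch_count > 1) {
      for (b in paste0("batch", 2:spec$batch_count)) {
        eff <- rnorm(G, 0, spec$batch_sdlog)
        lfc[, batch == b] <- lfc[, batch == b] + eff
      }
    }

    mu <- baseline * 2^lfc
    mu <- sweep(mu, 2, colSums(mu), "/")  # relative expression per cell
    lib <- spec$library_size_mean *
      rlnorm(n, meanlog = -spec$lib_sdlog^2 / 2, sdlog = spec$lib_sdlog)
    mu <- sweep(mu, 2, lib, "*")
    counts <- matrix(rnbinom(G * n, size = 1 / spec$dispersion, mu = mu),
                     nrow = G, dimnames = list(genes, cells))

    observed <- true_cluster
    flipped <- rep(FALSE, n)
    if (spec$flip_fraction > 0 && length(cl_names) > 1) {
      n_flip <- round(spec$flip_fraction * n)
      flip_idx <- sample(n, n_flip)
      observed[flip_idx] <- vapply(flip_idx, function(i)
        sample(setdiff(cl_names, true_cluster[i]), 1), character(1))
      flipped[flip_idx] <- TRUE
    }

    identity <- setNames(
      vapply(spec$cluster_profile,
             function(cl) if (is.null(cl$identity)) "neither" else cl$identity,
             character(1)), cl_names)

    ds <- expression_dataset(counts,
                             cell_meta = data.frame(cluster = observed,
                                                    batch = batch,
                                                    row.names = cells),
                             platform = "well")
    ds <- normalize_dataset(ds)
    de_genes <- lapply(spec$cluster_profile, function(cl) cl$program)
    names(de_genes) <- cl_names
    truth <- structure(
      list(cells = data.frame(cell = cells, cluster = true_cluster,
                              observed_cluster = observed, flipped = flipped,
                              latent_time = latent_time,
                              av_identity = identity[true_cluster],
                              phase = phase, batch = batch,
                              stringsAsFactors = FALSE),
           de_genes = de_genes, time_genes = spec$time_genes, spec = spec),
      class = "GroundTruth")
    list(dataset = ds, truth = truth)
  })
}

#' Default eight-cluster VEC spec
#'
#' Eight equal clusters named EP0-EP7 emulating an embryo-proper VEC
#' compartment: arterial marker programs (log2FC `marker_lfc`) planted in
#' EP2, EP3, EP5 and EP7, a venous program in EP6, and `n_cluster_genes`
#' cluster-private up-regulated genes per cluster so every cluster is
#' separable. EP1 and EP2 carry a latent time modulating `n_time_genes`
#' genes. Mirroring the mutual repression of the arterial and venous
#' transcriptional programs, identity clusters repress the opposite marker
#' set (`-marker_lfc`) and the remaining immature clusters sit mildly below
#' baseline (`-1`) on all arteriovenous markers.
#'
#' @param n_genes,n_cells dataset dimensions (defaults 2000 x 800).
#' @param marker_lfc planted log2 fold-change on arteriovenous markers.
#' @param n_cluster_genes private DE genes per cluster.
#' @param n_time_genes genes modulated along the EP1-EP2 latent time.
#' @param time_lfc log2 amplitude of the latent-time ramps.
#' @param seed RNG seed.
#' @param ... further arguments to [synthetic_spec()].
#' @return a `SyntheticSpec`.
#' @export
default_vec_spec <- function(n_genes = 2000, n_cells = 800, marker_lfc = 2,
                             n_cluster_genes = 20, n_time_genes = 50,
                             time_lfc = 2, seed = 1, ...) {
  markers <- av_marker_genes()
  arterial_clusters <- c("EP2", "EP3", "EP5", "EP7")
  cl_names <- paste0("EP", 0:7)
  profile <- lapply(seq_along(cl_names), function(i) {
    nm <- cl_names[i]
    own <- setNames(rep(2, n_cluster_genes),
                    sprintf("%s_deg_%02d", nm, seq_len(n_cluster_genes)))
    program <- own
    if (nm %in% arterial_clusters) {
      identity <- "arterial"
      program <- c(program,
                   setNames(rep(marker_lfc, length(markers$arterial)),
                            markers$arterial),
                   setNames(rep(-marker_lfc, length(markers$venous)),
                            markers$venous))
    } else if (nm == "EP6") {
      identity <- "venous"
      program <- c(program,
                   setNames(rep(marker_lfc, length(markers$venous)),
                            markers$venous),
                   setNames(rep(-marker_lfc, length(markers$arterial)),
                            markers$arterial))
    } else {
      identity <- "neither"
      program <- c(program,
                   setNames(rep(-1, length(c(markers$arterial, markers$venous))),
                            c(markers$arterial, markers$venous)))
    }
    list(name = nm, fraction = 1 / 8, program = program, identity = identity)
  })
  time_genes <- setNames(rep(time_lfc, n_time_genes),
                         sprintf("time_gene_%03d", seq_len(n_time_genes)))
  # synthetic stand-ins for the G1/S and G2/M programs (same set sizes as the
  # published core sets) so cycle_fraction > 0 can plant cycling cells
  marker_sets <- c(markers,
                   list(g1s = sprintf("g1s_gene_%02d", seq_len(43)),
                        g2m = sprintf("g2m_gene_%02d", seq_len(54))))
  synthetic_spec(n_genes = n_genes, n_cells = n_cells,
                 cluster_profile = profile,
                 latent_time_clusters = c("EP1", "EP2"),
                 time_genes = time_genes,
                 marker_sets = marker_sets, seed = seed, ...)
}

#' Generate a null dataset: labeled groups with identical distributions
#'
#' All clusters share the baseline program (no planted effects of any kind),
#' so no gene differs in distribution between the labeled groups; used for
#' type-I-error calibration of the DEG test.
#'
#' @param n_genes number of genes (default 1000).
#' @param cells_per_group cells in each group (> 0).
#' @param n_groups number of identically distributed groups (default 2).
#' @param seed RNG seed.
#' @param ... further arguments to [synthetic_spec()].
#' @return list with `dataset` and `truth` as in [generate_vec_dataset()].
#' @export
generate_null_dataset <- function(n_genes = 1000, cells_per_group = 100,
                                  n_groups = 2, seed = 1, ...) {
  if (any(cells_per_group <= 0))
    stop("invalid spec: cells_per_group must be > 0")
  if (n_groups < 2) stop("invalid spec: n_groups must be >= 2")
  profile <- lapply(seq_len(n_groups), function(i)
    list(name = paste0("grp", i), fraction = 1 / n_groups))
  spec <- synthetic_spec(n_genes = n_genes,
                         n_cells = cells_per_group * n_groups,
                         cluster_profile = profile, seed = seed, ...)
  generate_vec_dataset(spec)
}

#' Generate two linked "species" datasets with planted conserved markers
#'
#' Each species has three clusters (AEC1, AEC2, VeEC). Conserved genes are
#' up-regulated (log2FC `conserved_lfc`) in both arterial clusters of *both*
#' species; species-specific genes only in one species; venous markers in
#' VeEC of both. Gene namespaces differ (species B symbols are the species A
#' symbols suffixed `_b`) and are linked by the returned one-to-one homolog
#' map covering the full gene universe.
#'
#' @param n_genes genes per species (default 1000).
#' @param cells_per_cluster cells per cluster per species (default 200).
#' @param n_conserved planted conserved arterial genes (default 50).
#' @param n_specific species-specific arterial genes per species (default 25).
#' @param conserved_lfc planted log2 fold-change (default 2).
#' @param seed RNG seed (species B uses seed + 1).
#' @param ... further arguments to [synthetic_spec()].
#' @return list: `dataset_a`, `dataset_b`, `map` (homolog data.frame), `truth`
#'   (conserved / specific gene lists and both per-species truths).
#' @export
generate_two_species <- function(n_genes = 1000, cells_per_cluster = 200,
                                 n_conserved = 50, n_specific = 25,
                                 conserved_lfc = 2, seed = 1, ...) {
  conserved <- sprintf("cons_%03d", seq_len(n_conserved))
  spec_a_only <- sprintf("aspec_%03d", seq_len(n_specific))
  spec_b_only <- sprintf("bspec_%03d", seq_len(n_specific))
  venous <- sprintf("ven_%02d", seq_len(10))

  make_profile <- function(arterial_genes) {
    art <- setNames(rep(conserved_lfc, length(arterial_genes)), arterial_genes)
    ven <- setNames(rep(conserved_lfc, length(venous)), venous)
    list(list(name = "AEC1", fraction = 1 / 3, program = art,
              identity = "arterial"),
         list(name = "AEC2", fraction = 1 / 3, program = art,
              identity = "arterial"),
         list(name = "VeEC", fraction = 1 / 3, program = ven,
              identity = "venous"))
  }
  spec_a <- synthetic_spec(n_genes = n_genes,
                           n_cells = 3 * cells_per_cluster,
                           cluster_profile = make_profile(c(conserved,
                                                            spec_a_only)),
                           marker_sets = list(specific = spec_b_only),
                           seed = seed, ...)
  spec_b <- synthetic_spec(n_genes = n_genes,
                           n_cells = 3 * cells_per_cluster,
                           cluster_profile = make_profile(c(conserved,
                                                            spec_b_only)),
                           marker_sets = list(specific = spec_a_only),
                           seed = seed + 1, ...)
  a <- generate_vec_dataset(spec_a)
  b <- generate_vec_dataset(spec_b)
  # disjoint gene namespace for species B, linked one-to-one by the map
  b_names <- paste0(rownames(b$dataset$counts), "_b")
  rownames(b$dataset$counts) <- b_names
  rownames(b$dataset$norm) <- b_names
  rownames(b$dataset$gene_meta) <- b_names
  map <- data.frame(symbol_a = rownames(a$dataset$counts),
                    symbol_b = paste0(rownames(a$dataset$counts), "_b"),
                    stringsAsFactors = FALSE)
  truth <- structure(list(conserved = conserved,
                          specific_a = spec_a_only, specific_b = spec_b_only,
                          venous = venous, truth_a = a$truth,
                          truth_b = b$truth),
                     class = "GroundTruth")
  list(dataset_a = a$dataset, dataset_b = b$dataset, map = map, truth = truth)
}

#' Generate a mural-cell / VEC dataset pair with planted interactions
#'
#' Builds two datasets over a shared gene universe and a ligand-receptor
#' table of `n_planted` pairs that satisfy the interaction calling rule
#' (ligand strongly expressed in the mural cells, receptor in the VECs) plus
#' `n_decoy` pairs that violate it on at least one side (the decoy gene is
#' essentially silent in the population that should express it).
#'
#' @param n_genes shared gene universe size (default 1000).
#' @param n_mc,n_vec cells per compartment (defaults 200, 300).
#' @param n_planted,n_decoy planted and decoy pair counts (defaults 10, 10).
#' @param planted_lfc log2 boost of planted ligand/receptor genes (default 4).
#' @param seed RNG seed (VEC dataset uses seed + 1).
#' @param ... further arguments to [synthetic_spec()].
#' @return list: `vec`, `mc` (datasets), `pairs` (LR table containing planted
#'   and decoys, shuffled), `truth` (planted and decoy pair tables; planted
#'   direction is MC->VEC).
#' @export
generate_mc_vec_pair <- function(n_genes = 2000, n_mc = 200, n_vec = 300,
                                 n_planted = 10, n_decoy = 10,
                                 planted_lfc = 6, seed = 1, ...) {
  lig <- sprintf("Lig%02d", seq_len(n_planted + n_decoy))
  rec <- sprintf("Rec%02d", seq_len(n_planted + n_decoy))
  planted <- seq_len(n_planted)
  decoy <- n_planted + seq_len(n_decoy)
  # decoys alternate which side is broken
  decoy_break_ligand <- decoy[seq_along(decoy) %% 2 == 1]

  mc_up <- c(lig[planted], lig[setdiff(decoy, decoy_break_ligand)])
  vec_up <- c(rec[planted], rec[intersect(decoy, decoy_break_ligand)])
  silent <- c(lig[decoy_break_ligand], rec[setdiff(decoy, decoy_break_ligand)])

  mc_prog <- c(setNames(rep(planted_lfc, length(mc_up)), mc_up),
               setNames(rep(-10, length(c(vec_up, silent))), c(vec_up, silent)))
  vec_prog <- c(setNames(rep(planted_lfc, length(vec_up)), vec_up),
                setNames(rep(-10, length(c(mc_up, silent))), c(mc_up, silent)))

  mc_spec <- synthetic_spec(
    n_genes = n_genes, n_cells = n_mc,
    cluster_profile = list(list(name = "MC", fraction = 1,
                                program = mc_prog)),
    marker_sets = list(lr = c(lig, rec)), seed = seed, ...)
  vec_spec <- synthetic_spec(
    n_genes = n_genes, n_cells = n_vec,
    cluster_profile = list(list(name = "VEC", fraction = 1,
                                program = vec_prog)),
    marker_sets = list(lr = c(lig, rec)), seed = seed + 1, ...)
  mc <- generate_vec_dataset(mc_spec)
  vec <- generate_vec_dataset(vec_spec)
  pairs <- data.frame(ligand = lig, receptor = rec, stringsAsFactors = FALSE)
  truth <- structure(list(planted = pairs[planted, ],
                          decoys = pairs[decoy, ],
                          direction = "MC->VEC"),
                     class = "GroundTruth")
  list(vec = vec$dataset, mc = mc$dataset, pairs = pairs, truth = truth)
}

#' Write a ground-truth cell table as TSV
#'
#' Serializes the per-cell truth table next to a written dataset; never read
#' by pipeline stages, only by tests and audits.
#'
#' @param truth a `GroundTruth` with a `cells` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "GroundTruth"), !is.null(truth$cells))
  write.table(truth$cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
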