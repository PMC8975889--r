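#' Normalize UMI counts to log-scale expression
#'
#' Per cell, counts are rescaled to transcripts-per-million,
#' `TPM[g,c] = counts[g,c] / sum_g counts[g,c] * 1e6`, then log-transformed as
#' `log(TPM/s + 1)` (natural log) with `s = 10` for well-based protocols and
#' `s = 100` for droplet protocols. The divisor compensates for the gap
#' between the nominal per-million scale and the actual per-cell UMI depth of
#' each protocol, so that a transcript is not counted several times.
#'
#' @param dataset an [expression_dataset()].
#' @param platform `"well"` or `"droplet"`; defaults to the dataset's own.
#' @return the dataset with its `norm` layer filled.
#' @export
normalize_dataset <- function(dataset, platform = NULL) {
  if (is.null(platform)) platform <- dataset$platform
  platform <- match.arg(platform, c("well", "droplet"))
  s <- if (platform == "well") 10 else 100
  tot <- colSums(dataset$counts)
  if (any(tot == 0))
    stop("cells with zero total UMIs: ",
         paste(head(colnames(dataset$counts)[tot == 0], 10), collapse = ", "))
  # operate on the sparse triplet: zeros map to log(0/s + 1) = 0 exactly
  m <- as(dataset$counts, "TsparseMatrix")
  tpm_x <- m@x / tot[m@j + 1L] * 1e6
  norm <- sparseMatrix(i = m@i + 1L, j = m@j + 1L, x = log(tpm_x / s + 1),
                       dims = dim(m), dimnames = dimnames(m))
  dataset$norm <- as(norm, "CsparseMatrix")
  dataset$platform <- platform
  dataset
}

#' Quality-control threshold presets
#'
#' Named (min_genes, min_transcripts) presets for well-based datasets of
#' different sequencing depths; cells must exceed both strictly to be kept.
#'
#' @param name one of `"well_default"` (2000 genes, 100000 transcripts),
#'   `"well_shallow"` (2000, 50000), `"well_minimal"` (1000, 10000).
#' @return list with elements min_genes, min_transcripts.
#' @export
qc_preset <- function(name = c("well_default", "well_shallow", "well_minimal")) {
  name <- match.arg(name)
  switch(name,
         well_default = list(min_genes = 2000, min_transcripts = 100000),
         well_shallow = list(min_genes = 2000, min_transcripts = 50000),
         well_minimal = list(min_genes = 1000, min_transcripts = 10000))
}

#' Filter cells by detected genes and transcript totals
#'
#' A cell is retained iff it has strictly more than `min_genes` genes with at
#' least one count and strictly more than `min_transcripts` total UMIs
#' ("more than" semantics). Cell order is preserved; the operation is
#' idempotent.
#'
#' @param dataset an [expression_dataset()].
#' @param min_genes,min_transcripts non-negative integer thresholds; a preset
#'   from [qc_preset()] may be supplied via `preset` instead.
#' @param preset optional list with elements min_genes, min_transcripts.
#' @return list with elements `dataset` (retained cells) and `rejected`
#'   (character vector of removed cell identifiers).
#' @export
qc_filter <- function(dataset, min_genes = 2000, min_transcripts = 100000,
                      preset = NULL) {
  if (!is.null(preset)) {
    min_genes <- preset$min_genes
    min_transcripts <- preset$min_transcripts
  }
  stopifnot(min_genes >= 0, min_transcripts >= 0)
  n_genes <- colSums(dataset$counts > 0)
  n_umi <- colSums(dataset$counts)
  keep <- n_genes > min_genes & n_umi > min_transcripts
  if (!any(keep)) warning("no cells pass the QC thresholds")
  list(dataset = subset_dataset(dataset, cells = which(keep)),
       rejected = colnames(dataset$counts)[!keep])
}
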