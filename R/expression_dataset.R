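#' Construct an ExpressionDataset
#'
#' The central container of the package: a gene-by-cell UMI count matrix with
#' an optional normalized expression layer and per-cell / per-gene metadata.
#' Counts are stored sparse (`dgCMatrix`); the normalized layer, when present,
#' shares the counts' dimensions and dimnames and holds log-scale expression
#' values (see [normalize_dataset()]).
#'
#' @param counts gene x cell matrix of non-negative integer UMI counts, with
#'   unique rownames (gene symbols) and colnames (cell identifiers). Dense or
#'   sparse input is accepted and coerced to `dgCMatrix`.
#' @param cell_meta optional data.frame of per-cell annotations (stage,
#'   location, cluster, batch, ...); rownames must match `colnames(counts)`,
#'   or it must have one row per cell in order.
#' @param gene_meta optional data.frame of per-gene annotations.
#' @param norm optional pre-computed normalized layer with the same dimensions
#'   and dimnames as `counts`.
#' @param platform `"well"` (plate/well-based UMI protocols) or `"droplet"`;
#'   selects the TPM scaling divisor during normalization.
#' @return an object of class `ExpressionDataset`.
#' @seealso [normalize_dataset()], [qc_filter()], [read_dataset()]
#' @export
expression_dataset <- function(counts, cell_meta = NULL, gene_meta = NULL,
                               norm = NULL, platform = c("well", "droplet")) {
  platform <- match.arg(platform)
  counts <- .as_count_matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers: ",
         paste(head(unique(rownames(counts)[duplicated(rownames(counts))]), 5),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell identifiers: ",
         paste(head(unique(colnames(counts)[duplicated(colnames(counts))]), 5),
               collapse = ", "))
  cell_meta <- .align_meta(cell_meta, colnames(counts), "cell_meta")
  gene_meta <- .align_meta(gene_meta, rownames(counts), "gene_meta")
  if (!is.null(norm)) {
    norm <- as(as(Matrix(norm, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
    if (!identical(dim(norm), dim(counts)))
      stop("norm layer dimensions differ from counts")
    dimnames(norm) <- dimnames(counts)
    if (any(norm@x < 0)) stop("norm layer contains negative entries")
  }
  structure(
    list(counts = counts, norm = norm, cell_meta = cell_meta,
         gene_meta = gene_meta, platform = platform),
    class = "ExpressionDataset"
  )
}

.as_count_matrix <- function(counts) {
  m <- as(as(Matrix(as.matrix(counts), sparse = TRUE), "generalMatrix"),
          "CsparseMatrix")
  if (length(m@x)) {
    if (any(m@x < 0)) stop("negative count entries are not allowed")
    if (any(m@x != round(m@x))) stop("non-integer count entries are not allowed")
  }
  m
}

.align_meta <- function(meta, ids, what) {
  if (is.null(meta)) return(data.frame(row.names = ids))
  meta <- as.data.frame(meta)
  if (nrow(meta) != length(ids))
    stop(what, " has ", nrow(meta), " rows for ", length(ids), " identifiers")
  if (!is.null(rownames(meta)) && !identical(rownames(meta), as.character(seq_len(nrow(meta))))) {
    if (!setequal(rownames(meta), ids))
      stop(what, " rownames do not match identifiers")
    meta <- meta[ids, , drop = FALSE]
  } else {
    rownames(meta) <- ids
  }
  meta
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$counts), "genes x", ncol(x$counts), "cells",
      sprintf("(platform: %s)\n", x$platform))
  cat(" norm layer:", if (is.null(x$norm)) "absent" else "present", "\n")
  if (ncol(x$cell_meta))
    cat(" cell_meta:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Gene and cell identifiers of a dataset
#' @param dataset an [expression_dataset()].
#' @return character vector of identifiers, in matrix order.
#' @export
genes <- function(dataset) rownames(dataset$counts)

#' @rdname genes
#' @export
cells <- function(dataset) colnames(dataset$counts)

#' Subset a dataset by genes and/or cells
#'
#' Both layers and both metadata tables are subset consistently; order follows
#' the supplied index vectors.
#'
#' @param dataset an [expression_dataset()].
#' @param genes,cells character, integer or logical index vectors (NULL keeps all).
#' @return a new `ExpressionDataset`.
#' @export
subset_dataset <- function(dataset, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(dataset$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(dataset$counts)) else cells
  out <- dataset
  out$counts <- dataset$counts[gi, ci, drop = FALSE]
  if (!is.null(dataset$norm)) out$norm <- dataset$norm[gi, ci, drop = FALSE]
  out$cell_meta <- dataset$cell_meta[colnames(out$counts), , drop = FALSE]
  out$gene_meta <- dataset$gene_meta[rownames(out$counts), , drop = FALSE]
  out
}

#' Normalized expression of one gene across cells
#'
#' Convenience accessor returning a dense named vector; genes absent from the
#' dataset yield all zeros (useful when scoring reference gene lists that
#' exceed the measured gene space).
#'
#' @param dataset an [expression_dataset()] with a norm layer.
#' @param gene a single gene symbol.
#' @return named numeric vector over cells.
#' @export
gene_expression <- function(dataset, gene) {
  stopifnot(!is.null(dataset$norm))
  if (!gene %in% rownames(dataset$norm))
    return(setNames(numeric(ncol(dataset$norm)), colnames(dataset$norm)))
  setNames(as.numeric(dataset$norm[gene, ]), colnames(dataset$norm))
}
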