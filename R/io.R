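#' Read an expression dataset from disk
#'
#' Two plain-text layouts are supported. `"mtx"` expects a matrix-market
#' coordinate file `matrix.mtx` plus `genes.tsv` and `barcodes.tsv` (one
#' identifier per line) in the directory `path`, and optionally
#' `cell_meta.tsv`. `"tsv"` expects a single dense tab-separated file at
#' `path` with gene symbols in the first column and cell identifiers in the
#' header.
#'
#' @param path directory (mtx) or file (tsv).
#' @param format `"mtx"` or `"tsv"`.
#' @param platform passed to [expression_dataset()].
#' @return an `ExpressionDataset` (counts only; normalize separately).
#' @export
read_dataset <- function(path, format = c("mtx", "tsv"),
                         platform = c("well", "droplet")) {
  format <- match.arg(format)
  platform <- match.arg(platform)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- readMM(mtx)
    g <- readLines(gf)
    b <- readLines(bf)
    if (nrow(m) != length(g))
      stop("matrix has ", nrow(m), " rows but genes.tsv lists ", length(g))
    if (ncol(m) != length(b))
      stop("matrix has ", ncol(m), " columns but barcodes.tsv lists ", length(b))
    dimnames(m) <- list(g, b)
    meta <- NULL
    mf <- file.path(path, "cell_meta.tsv")
    if (file.exists(mf)) {
      meta <- read.delim(mf, row.names = 1, check.names = FALSE,
                         stringsAsFactors = FALSE)
    }
    expression_dataset(m, cell_meta = meta, platform = platform)
  } else {
    tab <- read.delim(path, row.names = 1, check.names = FALSE)
    expression_dataset(as.matrix(tab), platform = platform)
  }
}

#' Write an expression dataset to disk
#'
#' Inverse of [read_dataset()]: counts (and cell metadata, mtx format only)
#' are written so that a read round-trip preserves values, gene/cell order and
#' metadata. The norm layer is derived data and is not serialized.
#'
#' @param dataset an [expression_dataset()].
#' @param path directory (mtx; created if needed) or file (tsv).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    writeMM(dataset$counts, file.path(path, "matrix.mtx"))
    writeLines(rownames(dataset$counts), file.path(path, "genes.tsv"))
    writeLines(colnames(dataset$counts), file.path(path, "barcodes.tsv"))
    if (ncol(dataset$cell_meta))
      write.table(dataset$cell_meta, file.path(path, "cell_meta.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
  } else {
    tab <- as.matrix(dataset$counts)
    out <- data.frame(gene = rownames(tab), tab, check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene-signature file (one symbol per line)
#' @param path text file; blank lines and lines starting with `#` are skipped.
#' @return character vector of unique symbols, input order preserved.
#' @export
read_signature <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read a ligand-receptor pair table
#' @param path two-column TSV with header `ligand<TAB>receptor`.
#' @return data.frame with columns ligand, receptor; duplicate rows dropped.
#' @export
read_lr_pairs <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% colnames(tab)))
    stop("LR table needs columns 'ligand' and 'receptor'")
  unique(tab[, c("ligand", "receptor")])
}

#' Read a two-column homolog map
#' @param path TSV whose first two columns are species-A and species-B symbols.
#' @return data.frame with columns symbol_a, symbol_b; fully duplicated rows dropped.
#' @export
read_homolog_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("homolog map needs two columns")
  out <- unique(tab[, 1:2])
  colnames(out) <- c("symbol_a", "symbol_b")
  out
}
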