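# small deterministic fixtures shared across test files

# dense toy dataset: counts are a fixed small matrix; normalized on request
toy_dataset <- function(counts = NULL, platform = "well", normalized = TRUE) {
  if (is.null(counts)) {
    counts <- matrix(c(10, 0, 5,
                       0, 20, 5,
                       90, 80, 90) * 10,
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("gA", "gB", "gC"),
                                     c("c1", "c2", "c3")))
  }
  ds <- expression_dataset(counts, platform = platform)
  if (normalized) ds <- normalize_dataset(ds) else ds
}

# dataset built from an explicit norm layer (counts = ceiling of expm1(norm))
norm_dataset <- function(norm) {
  counts <- ceiling(expm1(norm))
  ds <- expression_dataset(counts)
  ds$norm <- methods::as(methods::as(Matrix::Matrix(norm, sparse = TRUE),
                                     "generalMatrix"), "CsparseMatrix")
  dimnames(ds$norm) <- dimnames(ds$counts)
  ds
}

# two well-separated expression clusters with optional ambiguous duplicates;
# returns a normalized dataset plus the true labels
two_cluster_dataset <- function(n_per = 50, n_genes = 60, shift = 3, seed = 11,
                                n_ambiguous = 0) {
  set.seed(seed)
  na <- n_per; nb <- n_per
  base <- matrix(abs(rnorm(n_genes * (na + nb + n_ambiguous), 2, 0.4)),
                 nrow = n_genes)
  half <- seq_len(n_genes / 2)
  base[half, seq_len(na)] <- base[half, seq_len(na)] + shift
  base[-half, na + seq_len(nb)] <- base[-half, na + seq_len(nb)] + shift
  if (n_ambiguous > 0) {
    amb_cols <- na + nb + seq_len(n_ambiguous)
    base[, amb_cols] <- base[, amb_cols] + shift / 2  # halfway profile
  }
  dimnames(base) <- list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("c%03d", seq_len(ncol(base))))
  labels <- c(rep("A", na), rep("B", nb),
              rep(c("A", "B"), length.out = n_ambiguous))
  names(labels) <- colnames(base)
  list(dataset = norm_dataset(base), labels = factor(labels))
}
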