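test_that("construction validates identifiers and count domain", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  ds <- expression_dataset(m)
  expect_s3_class(ds, "ExpressionDataset")
  expect_equal(dim(ds), c(2L, 3L))
  expect_equal(genes(ds), c("g1", "g2"))

  bad <- m; rownames(bad) <- c("g1", "g1")
  expect_error(expression_dataset(bad), "duplicate gene")
  bad <- m; bad[1, 1] <- -1
  expect_error(expression_dataset(bad), "negative")
  bad <- m; bad[1, 1] <- 1.5
  expect_error(expression_dataset(bad), "non-integer")
})

test_that("write/read round-trips counts, order and metadata in both formats", {
  set.seed(5)
  m <- matrix(rpois(200, 2), 20, 10,
              dimnames = list(sprintf("g%02d", 20:1),   # non-alphabetical order
                              sprintf("c%02d", 10:1)))
  meta <- data.frame(cluster = rep(c("x", "y"), 5), row.names = colnames(m))
  ds <- expression_dataset(m, cell_meta = meta)

  d_mtx <- withr::local_tempdir()
  write_dataset(ds, d_mtx, "mtx")
  back <- read_dataset(d_mtx, "mtx")
  expect_equal(as.matrix(back$counts), as.matrix(ds$counts))
  expect_equal(genes(back), genes(ds))
  expect_equal(cells(back), cells(ds))
  expect_equal(back$cell_meta$cluster, meta$cluster)

  f_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, f_tsv, "tsv")
  back2 <- read_dataset(f_tsv, "tsv")
  expect_equal(as.matrix(back2$counts), as.matrix(ds$counts))
})

test_that("mtx reader rejects dimension mismatches and negative entries", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 2", "1 1 5", "2 2 -1"), file.path(d, "matrix.mtx"))
  writeLines(c("g1", "g2"), file.path(d, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(d, "barcodes.tsv"))
  expect_error(read_dataset(d, "mtx"), "negative")

  writeLines(c("g1", "g2", "g3"), file.path(d, "genes.tsv"))
  expect_error(read_dataset(d, "mtx"), "genes.tsv")
})

test_that("normalization matches the per-cell TPM formula", {
  # cell total 100000 UMIs, gene with 10 UMIs, well platform:
  # TPM = 100, norm = ln(100/10 + 1) = ln(11)
  cnt <- matrix(c(10, 99990, 50, 49950), 2, 2,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
  ds <- normalize_dataset(expression_dataset(cnt), "well")
  expect_equal(ds$norm["g1", "c1"], log(11))
  # droplet scaling uses s = 100
  dd <- normalize_dataset(expression_dataset(cnt), "droplet")
  expect_equal(dd$norm["g1", "c1"], log(2))
  # zero counts stay exactly zero
  cnt2 <- matrix(c(0, 10, 5, 5), 2, 2,
                 dimnames = list(c("g1", "g2"), c("c1", "c2")))
  dz <- normalize_dataset(expression_dataset(cnt2))
  expect_identical(dz$norm["g1", "c1"], 0)
})

test_that("normalization agrees with an independent per-cell loop and conserves TPM", {
  set.seed(42)
  cnt <- matrix(rpois(300, 5), 30, 10,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:10)))
  cnt[1, ] <- cnt[1, ] + 1  # no zero-total cells
  ds <- normalize_dataset(expression_dataset(cnt), "well")
  # brute-force oracle: scalar loop over entries
  oracle <- matrix(0, 30, 10)
  for (j in 1:10) {
    tot <- sum(cnt[, j])
    for (i in 1:30) oracle[i, j] <- log((cnt[i, j] / tot * 1e6) / 10 + 1)
  }
  expect_lt(max(abs(as.matrix(ds$norm) - oracle)), 1e-12)
  tpm <- sweep(as.matrix(cnt), 2, colSums(cnt), "/") * 1e6
  expect_true(all(abs(colSums(tpm) - 1e6) < 1e-6 * 1e6))
})

test_that("normalization errors on zero-total cells, naming them", {
  cnt <- matrix(c(0, 0, 3, 4), 2, 2,
                dimnames = list(c("g1", "g2"), c("empty", "ok")))
  expect_error(normalize_dataset(expression_dataset(cnt)), "empty")
})

test_that("QC filtering uses strict 'more than' thresholds and is idempotent", {
  # cells with (genes detected, total UMIs):
  # (2500, 120000) kept; (1500, 200000) and (3000, 50000) rejected;
  # a cell exactly at (2000, 100000) rejected under strict inequality
  mk_cell <- function(n_genes, total) {
    v <- numeric(4000)
    v[seq_len(n_genes)] <- 1
    v[1] <- v[1] + (total - n_genes)
    v
  }
  cnt <- cbind(a = mk_cell(2500, 120000), b = mk_cell(1500, 200000),
               c = mk_cell(3000, 50000), d = mk_cell(2000, 100000))
  rownames(cnt) <- sprintf("g%04d", seq_len(4000))
  ds <- expression_dataset(cnt)
  res <- qc_filter(ds, preset = qc_preset("well_default"))
  expect_equal(cells(res$dataset), "a")
  expect_setequal(res$rejected, c("b", "c", "d"))
  # idempotent
  res2 <- qc_filter(res$dataset, preset = qc_preset("well_default"))
  expect_equal(cells(res2$dataset), cells(res$dataset))
  expect_length(res2$rejected, 0)
  # (0, 0) keeps every cell with at least one count
  res0 <- qc_filter(ds, 0, 0)
  expect_equal(ncol(res0$dataset$counts), 4)
})

test_that("normalization is monotone in the raw count at fixed cell total", {
  # two cells, same total, gene counts 5 < 9
  cnt <- matrix(c(5, 95, 9, 91), 2, 2,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
  ds <- normalize_dataset(expression_dataset(cnt))
  expect_lt(ds$norm["g1", "c1"], ds$norm["g1", "c2"])
})

test_that("signature, LR-pair and homolog-map readers parse plain text", {
  sig <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# arterial markers", "Gja5", "", "Dll4", "Gja5"), sig)
  expect_equal(read_signature(sig), c("Gja5", "Dll4"))

  lr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ligand\treceptor", "Jag1\tNotch1", "Jag1\tNotch1",
               "Dll4\tNotch1"), lr)
  tab <- read_lr_pairs(lr)
  expect_equal(nrow(tab), 2)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "x\ty"), bad)
  expect_error(read_lr_pairs(bad), "ligand")

  hm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mouse\thuman", "Gja5\tGJA5", "Nrp2\tNRP2"), hm)
  map <- read_homolog_map(hm)
  expect_equal(colnames(map), c("symbol_a", "symbol_b"))
  expect_equal(nrow(map), 2)
})
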