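# fast config for unit tests; the full-default run lives in test-acceptance.R
fast_config <- function(seed = 1)
  refinement_config(n_runs = 5, n_trees = 200, seed = seed)

test_that("config invariants are enforced", {
  expect_error(refinement_config(keep_vote_min = 0.4), "keep_vote_min")
  expect_error(refinement_config(train_vote_min = 0.5, keep_vote_min = 0.55))
  expect_s3_class(refinement_config(), "RefinementConfig")
})

test_that("hierarchical first split recovers correlation blocks", {
  # two blocks with within-block correlation ~1 and between ~ -1
  base <- sin(seq(0, 4 * pi, length.out = 20))
  norm <- cbind(b1a = 2 + base, b1b = 2 + 0.98 * base, b1c = 2 + 1.02 * base,
                b2a = 2 - base, b2b = 2 - 0.97 * base)
  rownames(norm) <- sprintf("g%02d", 1:20)
  sp <- initial_split(norm_dataset(pmax(norm, 0)))
  expect_equal(length(unique(sp[1:3])), 1)
  expect_equal(length(unique(sp[4:5])), 1)
  expect_false(sp[[1]] == sp[[4]])
  # three cells split 1/2 at the root
  sp3 <- initial_split(norm_dataset(pmax(norm[, c(1, 2, 4)], 0)))
  expect_setequal(as.integer(table(sp3)), c(1, 2))
})

test_that("constant cell profiles are assigned by nearest neighbour with warning", {
  tc <- two_cluster_dataset(n_per = 10, seed = 77)
  norm <- as.matrix(tc$dataset$norm)
  norm <- cbind(norm, flatcell = rep(2, nrow(norm)))
  expect_warning(sp <- initial_split(norm_dataset(norm)), "constant")
  expect_false(is.na(sp["flatcell"]))
})

test_that("feature selection finds planted informative genes", {
  tc <- two_cluster_dataset(n_per = 40, n_genes = 100, seed = 78)
  # genes g001..g050 and g051..g100 are informative by construction; add nulls
  set.seed(78)
  nulls <- matrix(abs(rnorm(400 * 80, 2, 0.4)), 400,
                  dimnames = list(sprintf("null%03d", 1:400),
                                  cells(tc$dataset)))
  ds <- norm_dataset(rbind(as.matrix(tc$dataset$norm), nulls))
  set.seed(5)
  fs <- rf_feature_select(ds, tc$labels, fast_config())
  expect_gte(mean(!startsWith(fs$selected, "null")), 0.8)
  # permuted labels: selection is uninformative
  set.seed(6)
  perm <- sample(tc$labels)
  names(perm) <- names(tc$labels)
  fs0 <- rf_feature_select(ds, perm, fast_config())
  expect_lt(mean(!startsWith(fs0$selected, "null")),
            mean(!startsWith(fs$selected, "null")))
})

test_that("label adjustment restores planted flips on separable data", {
  tc <- two_cluster_dataset(n_per = 60, seed = 79)
  truth <- tc$labels
  set.seed(8)
  flipped <- sample(length(truth), 12)
  noisy <- truth
  noisy[flipped] <- ifelse(truth[flipped] == "A", "B", "A")
  set.seed(9)
  out <- refine_labels(tc$dataset, noisy, genes(tc$dataset), fast_config())
  expect_gte(mean(out[flipped] == truth[flipped]), 0.95)
  expect_true(all(out[-flipped] == truth[-flipped]))
})

test_that("degenerate inputs abort adjustment instead of refining", {
  # all cells identical: no signal, labels must come back unchanged
  norm <- matrix(2, 20, 12, dimnames = list(sprintf("g%02d", 1:20),
                                            sprintf("c%02d", 1:12)))
  ds <- norm_dataset(norm)
  labels <- factor(rep(c("A", "B"), 6), levels = c("A", "B"))
  names(labels) <- cells(ds)
  set.seed(10)
  expect_warning(out <- refine_labels(ds, labels, genes(ds), fast_config()),
                 "constant|confident")
  expect_identical(out, labels)
  expect_error(cv_filter(ds, labels, genes(ds), fast_config()), "constant")
})

test_that("ambiguous duplicated cells are discarded at the vote cutoff", {
  tc <- two_cluster_dataset(n_per = 30, seed = 80, n_ambiguous = 2)
  set.seed(11)
  rr <- cv_filter(tc$dataset, tc$labels, genes(tc$dataset), fast_config(),
                  diagnostics = TRUE)
  amb <- tail(cells(tc$dataset), 2)
  expect_true(all(amb %in% rr$discarded))
  expect_true(all(rr$mean_vote[amb] < 0.55))
  # clean cells all kept
  clean <- setdiff(cells(tc$dataset), amb)
  expect_lte(length(setdiff(rr$discarded, amb)), 2)
  # discard rule exactness from diagnostics
  expect_setequal(rr$discarded, names(which(rr$mean_vote < 0.55)))
  expect_equal(dim(rr$vote_matrix), c(62, 5))
})

test_that("raising keep_vote_min never shrinks the discarded set", {
  tc <- two_cluster_dataset(n_per = 25, seed = 81, n_ambiguous = 4)
  run_with <- function(kmin) {
    set.seed(12)
    cfg <- refinement_config(n_runs = 3, n_trees = 150, keep_vote_min = kmin,
                             train_vote_min = max(kmin, 0.6), seed = 12)
    cv_filter(tc$dataset, tc$labels, genes(tc$dataset), cfg)
  }
  d55 <- run_with(0.55)$discarded
  d60 <- run_with(0.60)$discarded
  expect_true(all(d55 %in% d60))
})

test_that("full fine-tuning corrects flips, is deterministic, aborts on null", {
  spec <- synthetic_spec(
    n_genes = 300, n_cells = 200,
    cluster_profile = list(
      list(name = "EP6", fraction = 0.5,
           program = setNames(rep(1.5, 50), sprintf("six%02d", 1:50))),
      list(name = "EP7", fraction = 0.5,
           program = setNames(rep(1.5, 50), sprintf("sev%02d", 1:50)))),
    flip_fraction = 0.1, seed = 21)
  res <- generate_vec_dataset(spec)
  cfg <- refinement_config(n_runs = 5, n_trees = 200, seed = 4)
  rr <- fine_tune_clusters(res$dataset, res$dataset$cell_meta$cluster, cfg)
  truth <- res$truth$cells$cluster
  kept <- rr$final_label != "discarded"
  # map refined A/B to true cluster names by majority
  tab <- table(rr$final_label[kept], truth[kept])
  mapping <- colnames(tab)[apply(tab[c("A", "B"), ], 1, which.max)]
  mapped <- setNames(mapping, c("A", "B"))[as.character(rr$final_label[kept])]
  expect_gte(mean(mapped == truth[kept]), 0.95)
  rr2 <- fine_tune_clusters(res$dataset, res$dataset$cell_meta$cluster, cfg)
  expect_identical(rr$final_label, rr2$final_label)
  expect_identical(rr$mean_vote, rr2$mean_vote)

  # identical programs: no DEGs, aborted with warning
  nul <- generate_null_dataset(n_genes = 300, cells_per_group = 60, seed = 22)
  expect_warning(
    rn <- fine_tune_clusters(nul$dataset, nul$dataset$cell_meta$cluster, cfg),
    "aborted")
  expect_true(rn$aborted)
})
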