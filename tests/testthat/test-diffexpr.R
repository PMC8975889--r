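test_that("rank-sum p values match wilcox.test with the normal approximation", {
  set.seed(51)
  n1 <- 30; n2 <- 25
  norm <- matrix(round(abs(rnorm(40 * (n1 + n2), 2, 1)), 1), 40,
                 dimnames = list(sprintf("g%02d", 1:40),
                                 sprintf("c%02d", seq_len(n1 + n2))))
  ds <- norm_dataset(norm)
  g1 <- cells(ds)[seq_len(n1)]; g2 <- cells(ds)[n1 + seq_len(n2)]
  deg <- wilcoxon_deg(ds, g1, g2, min_pct = 0, fc_min = 1, alpha = 1)
  ref <- vapply(deg$gene, function(g)
    wilcox.test(norm[g, g1], norm[g, g2], exact = FALSE, correct = FALSE)$p.value,
    numeric(1))
  expect_lt(max(abs(deg$p - ref)), 1e-10)
})

test_that("expressing-fraction filter and group checks are enforced", {
  norm <- matrix(0, 3, 20, dimnames = list(c("rare", "ok", "flat"),
                                           sprintf("c%02d", 1:20)))
  norm["rare", c(1, 11)] <- 2         # 10% in each group
  norm["ok", 1:14] <- 2               # >= 25% in group1
  ds <- norm_dataset(norm)
  g1 <- sprintf("c%02d", 1:10); g2 <- sprintf("c%02d", 11:20)
  deg <- wilcoxon_deg(ds, g1, g2)
  expect_false("rare" %in% deg$gene)
  expect_true("ok" %in% deg$gene)
  expect_error(wilcoxon_deg(ds, g1, c(g2, "c01")), "overlap")
})

test_that("identical groups retain nothing; symmetry flips direction, keeps p", {
  set.seed(52)
  block <- matrix(abs(rnorm(30 * 15, 2, 1)), 30)
  norm <- cbind(block, block)
  dimnames(norm) <- list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:30))
  ds <- norm_dataset(norm)
  g1 <- sprintf("c%02d", 1:15); g2 <- sprintf("c%02d", 16:30)
  deg <- wilcoxon_deg(ds, g1, g2, min_pct = 0)
  expect_false(any(deg$retained))

  norm2 <- norm; norm2[1:10, 1:15] <- norm2[1:10, 1:15] + 2
  ds2 <- norm_dataset(norm2)
  a <- wilcoxon_deg(ds2, g1, g2, min_pct = 0, fc_min = 1, alpha = 1)
  b <- wilcoxon_deg(ds2, g2, g1, min_pct = 0, fc_min = 1, alpha = 1)
  expect_equal(a$p, b$p[match(a$gene, b$gene)])
  expect_true(all(a$direction != b$direction[match(a$gene, b$gene)] |
                    a$log_fc == 0))
})

test_that("planted DEGs are recovered and null genes controlled", {
  spec <- synthetic_spec(
    n_genes = 500, n_cells = 200,
    cluster_profile = list(
      list(name = "hi", fraction = 0.5,
           program = setNames(rep(2, 40), sprintf("de%02d", 1:40))),
      list(name = "lo", fraction = 0.5)),
    seed = 61)
  res <- generate_vec_dataset(spec)
  cl <- res$dataset$cell_meta$cluster
  deg <- wilcoxon_deg(res$dataset, cells(res$dataset)[cl == "hi"],
                      cells(res$dataset)[cl == "lo"])
  planted <- sprintf("de%02d", 1:40)
  hits <- deg$gene[deg$retained & deg$direction == "up"]
  expect_gte(mean(planted %in% hits), 0.9)
  null_genes <- setdiff(genes(res$dataset), planted)
  expect_lte(mean(null_genes %in% deg$gene[deg$retained]), 0.05)
})

test_that("BH adjustment matches an independently coded step-up procedure", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- numeric(m)
    running <- 1
    for (k in seq_along(o)) {
      i <- o[k]
      rank_i <- m - k + 1
      running <- min(running, p[i] * m / rank_i)
      adj[i] <- running
    }
    adj
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(53)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone in sorted raw p
  p <- sort(runif(100))
  expect_true(all(diff(bh_adjust(p)) >= 0))
})

test_that("Fisher combination matches the chi-square closed form", {
  # two p = 0.05: X = -2 * 2 * ln(0.05), df 4
  x <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(fisher_combine(c(0.05, 0.05)),
               pchisq(x, df = 4, lower.tail = FALSE))
  expect_lt(abs(fisher_combine(c(0.05, 0.05)) - 0.0175), 5e-4)
  expect_equal(fisher_combine(1), 1)
  # k = 1 is the identity
  for (p in c(0.001, 0.2, 0.77)) expect_equal(fisher_combine(p), p)
  expect_warning(out <- fisher_combine(c(0, 0.5)), "clamped")
  expect_true(out >= 0 && out <= 1)
})

test_that("Fisher combination of uniform p values is uniform", {
  set.seed(54)
  draws <- replicate(5000, fisher_combine(runif(3)))
  ks <- suppressWarnings(ks.test(draws, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("moving-average smoothing matches a direct loop and its edge cases", {
  x <- c(rep(4, 30))
  expect_equal(smooth_over_cells(x, window = 20), x)
  set.seed(55)
  y <- rnorm(45)
  expect_equal(smooth_over_cells(y, window = 1), y)
  ord <- sample(45)
  sm <- smooth_over_cells(y, ord, window = 7)
  # oracle: loop on the reordered series
  v <- y[ord]
  ref <- numeric(45)
  for (i in 1:45) ref[i] <- mean(v[max(1, i - 3):min(45, i + 3)])
  expect_lt(max(abs(sm[ord] - ref)), 1e-12)
  expect_error(smooth_over_cells(y, window = 0), "window")
})

test_that("pattern genes are categorized by stage-wise up-regulation", {
  spec <- synthetic_spec(
    n_genes = 400, n_cells = 240,
    cluster_profile = list(
      list(name = "EP1", fraction = 1 / 3),
      list(name = "EP2", fraction = 1 / 3,
           program = setNames(rep(2, 15), sprintf("seg%02d", 1:15))),
      list(name = "EP3", fraction = 1 / 3,
           program = c(setNames(rep(2, 15), sprintf("seg%02d", 1:15)),
                       setNames(rep(2, 15), sprintf("str%02d", 1:15))))),
    seed = 62)
  res <- generate_vec_dataset(spec)
  tab <- pattern_genes(res$dataset, res$dataset$cell_meta$cluster)
  seg <- tab$gene[tab$category == "arterial_segregation"]
  str <- tab$gene[tab$category == "arterial_strengthening"]
  expect_gte(mean(sprintf("seg%02d", 1:15) %in% seg), 0.85)
  expect_gte(mean(sprintf("str%02d", 1:15) %in% str), 0.85)
  # segregation genes stay up in EP3, so they never land in strengthening-only
  expect_length(intersect(seg, str), 0)
  expect_error(pattern_genes(res$dataset, res$dataset$cell_meta$cluster,
                             early = "EP9"), "EP9")
})

test_that("type-I error on null data is calibrated", {
  nd <- generate_null_dataset(n_genes = 1000, cells_per_group = 100, seed = 63)
  cl <- nd$dataset$cell_meta$cluster
  deg <- wilcoxon_deg(nd$dataset, cells(nd$dataset)[cl == "grp1"],
                      cells(nd$dataset)[cl == "grp2"], min_pct = 0)
  expect_gte(nrow(deg), 1000)
  rate <- mean(deg$p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
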