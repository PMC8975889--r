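#' Configuration for supervised cluster refinement
#'
#' Defaults follow the published procedure: 100 runs of 10-fold random-forest
#' cross validation, a training-set vote cutoff of 0.6, a retention cutoff of
#' 0.55 (cells whose mean held-out vote probability for their own label falls
#' below it are discarded as ambiguous), and forests of 500 trees.
#'
#' @param n_folds folds per cross-validation run.
#' @param n_runs number of CV repetitions.
#' @param train_vote_min out-of-bag vote probability above which a cell joins
#'   the training set during label adjustment.
#' @param keep_vote_min mean held-out vote probability below which a cell is
#'   discarded.
#' @param n_trees trees per forest.
#' @param seed RNG seed for the full orchestration.
#' @return list of class `RefinementConfig`.
#' @export
refinement_config <- function(n_folds = 10, n_runs = 100, train_vote_min = 0.6,
                              keep_vote_min = 0.55, n_trees = 500, seed = 1) {
  stopifnot(keep_vote_min >= 0.5, keep_vote_min <= train_vote_min,
            train_vote_min < 1, n_folds >= 2, n_runs >= 1, n_trees >= 1)
  structure(list(n_folds = n_folds, n_runs = n_runs,
                 train_vote_min = train_vote_min,
                 keep_vote_min = keep_vote_min,
                 n_trees = n_trees, seed = seed),
            class = "RefinementConfig")
}

#' Two-way hierarchical first split on correlation distance
#'
#' Cells are clustered hierarchically on the distance `1 - Pearson
#' correlation` of their normalized profiles over the given genes (average
#' linkage) and the dendrogram is cut at its root into exactly two clusters.
#' Cells with a constant profile (undefined correlation) are assigned to the
#' cluster of their nearest non-degenerate neighbour by Euclidean distance,
#' with a warning.
#'
#' @param dataset a normalized [expression_dataset()].
#' @param cells cell identifiers to split (default: all).
#' @param genes gene symbols to use (default: all).
#' @return named factor with levels `"A"`, `"B"` over the cells.
#' @export
initial_split <- function(dataset, cells = NULL, genes = NULL) {
  stopifnot(!is.null(dataset$norm))
  if (is.null(cells)) cells <- colnames(dataset$norm)
  if (is.null(genes)) genes <- rownames(dataset$norm)
  stopifnot(length(cells) >= 3, length(genes) >= 2)
  x <- as.matrix(dataset$norm[genes, cells, drop = FALSE])
  sds <- apply(x, 2, sd)
  ok <- sds > 0
  if (sum(ok) < 3) stop("fewer than 3 cells with non-constant profiles")
  cc <- cor(x[, ok, drop = FALSE])
  hc <- hclust(as.dist(1 - cc), method = "average")
  grp <- cutree(hc, k = 2)
  labels <- setNames(rep(NA_character_, length(cells)), cells)
  labels[colnames(cc)] <- c("A", "B")[grp]
  if (any(!ok)) {
    warning(sum(!ok), " constant cell profile(s) assigned by nearest neighbour")
    for (cell in cells[!ok]) {
      d <- colSums((x[, ok, drop = FALSE] - x[, cell])^2)
      labels[cell] <- labels[names(which.min(d))]
    }
  }
  factor(labels, levels = c("A", "B"))
}

# stratified fold assignment: within each class, shuffled cells are dealt
# round-robin into folds
make_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

.check_two_classes <- function(labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("exactly two classes required")
  labels
}

#' Cross-validated random-forest feature selection
#'
#' Across `n_folds` stratified folds a random forest is fit on the training
#' part and its impurity (Gini) importances are accumulated; genes are ranked
#' by mean importance and the selected set is the genes whose mean importance
#' exceeds the overall mean importance.
#'
#' @param dataset a normalized [expression_dataset()].
#' @param labels two-class factor over the dataset's cells (named or in order).
#' @param config a [refinement_config()].
#' @return list with `ranking` (data.frame gene, importance, descending) and
#'   `selected` (character vector).
#' @export
rf_feature_select <- function(dataset, labels, config = refinement_config()) {
  labels <- .check_two_classes(.cell_labels(dataset, labels))
  n_folds <- config$n_folds
  min_class <- min(table(labels))
  if (min_class < n_folds) {
    warning("smallest class has ", min_class, " cells; reducing folds")
    n_folds <- max(2, min_class)
  }
  x <- t(as.matrix(dataset$norm))
  colnames(x) <- rownames(dataset$norm)
  if (all(apply(x, 2, sd) == 0))
    stop("all genes are constant; feature selection is undefined")
  fold <- make_folds(labels, n_folds)
  imp <- matrix(0, nrow = ncol(x), ncol = n_folds,
                dimnames = list(colnames(x), NULL))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    rf <- randomForest::randomForest(x[tr, , drop = FALSE],
                                     droplevels(labels[tr]),
                                     ntree = config$n_trees)
    imp[, f] <- rf$importance[, "MeanDecreaseGini"]
  }
  mean_imp <- rowMeans(imp)
  ranking <- data.frame(gene = names(mean_imp), importance = mean_imp,
                        stringsAsFactors = FALSE, row.names = NULL)
  ranking <- ranking[order(-ranking$importance), ]
  list(ranking = ranking,
       selected = ranking$gene[ranking$importance > mean(mean_imp)])
}

#' Vote-probability-guided label adjustment
#'
#' A forest is fit on all cells over the feature genes; each cell's internal
#' vote probability is the out-of-bag fraction of trees voting for its current
#' label. Cells with vote probability above `train_vote_min` form the
#' training set of an optimal classifier that re-predicts the remaining
#' cells. If either class contributes no confident training cell, refinement
#' is aborted and the input labels are returned with a warning.
#'
#' @param dataset a normalized [expression_dataset()].
#' @param labels two-class factor over cells.
#' @param features feature gene symbols (non-empty).
#' @param config a [refinement_config()].
#' @return named factor of adjusted labels.
#' @export
refine_labels <- function(dataset, labels, features,
                          config = refinement_config()) {
  stopifnot(length(features) > 0)
  labels <- .check_two_classes(.cell_labels(dataset, labels))
  x <- t(as.matrix(dataset$norm[features, , drop = FALSE]))
  if (all(apply(x, 2, sd) == 0)) {
    warning("all feature genes are constant; labels returned unchanged")
    return(labels)
  }
  rf <- randomForest::randomForest(x, labels, ntree = config$n_trees)
  vote_own <- rf$votes[cbind(seq_along(labels), as.integer(labels))]
  confident <- vote_own > config$train_vote_min
  if (any(tapply(confident, labels, sum) == 0)) {
    warning("a class has no confident training cells; labels returned unchanged")
    return(labels)
  }
  fit <- randomForest::randomForest(x[confident, , drop = FALSE],
                                    droplevels(labels[confident]),
                                    ntree = config$n_trees)
  out <- labels
  if (any(!confident))
    out[!confident] <- predict(fit, x[!confident, , drop = FALSE])
  out
}

#' Ambiguity filtering by repeated cross-validated vote probabilities
#'
#' Runs `n_runs` independent rounds of stratified `n_folds`-fold random-forest
#' cross validation; in each round every cell's held-out vote probability for
#' its current label is recorded. Cells whose mean vote probability over the
#' runs falls below `keep_vote_min` are discarded as ambiguous; the rest keep
#' their labels.
#'
#' @param dataset a normalized [expression_dataset()].
#' @param labels two-class factor over cells.
#' @param features feature gene symbols.
#' @param config a [refinement_config()].
#' @param diagnostics keep the per-run vote matrix (cells x runs)?
#' @return list of class `RefinementResult`: `final_label` (factor with the
#'   two class levels plus `"discarded"`), `mean_vote`, `discarded` (cell
#'   identifiers), `features`, and optionally `vote_matrix`.
#' @export
cv_filter <- function(dataset, labels, features,
                      config = refinement_config(), diagnostics = FALSE) {
  stopifnot(length(features) > 0)
  labels <- .check_two_classes(.cell_labels(dataset, labels))
  x <- t(as.matrix(dataset$norm[features, , drop = FALSE]))
  if (all(apply(x, 2, sd) == 0))
    stop("all feature genes are constant; vote probabilities are undefined")
  n_folds <- config$n_folds
  min_class <- min(table(labels))
  if (min_class < n_folds) {
    warning("smallest class has ", min_class, " cells; reducing folds")
    n_folds <- max(2, min_class)
  }
  votes <- matrix(NA_real_, nrow = length(labels), ncol = config$n_runs,
                  dimnames = list(names(labels), NULL))
  for (run in seq_len(config$n_runs)) {
    fold <- make_folds(labels, n_folds)
    for (f in seq_len(n_folds)) {
      te <- fold == f
      rf <- randomForest::randomForest(x[!te, , drop = FALSE],
                                       droplevels(labels[!te]),
                                       ntree = config$n_trees)
      prob <- predict(rf, x[te, , drop = FALSE], type = "prob")
      votes[te, run] <- prob[cbind(seq_len(sum(te)),
                                   match(as.character(labels[te]),
                                         colnames(prob)))]
    }
  }
  mean_vote <- rowMeans(votes)
  keep <- mean_vote >= config$keep_vote_min
  final <- factor(ifelse(keep, as.character(labels), "discarded"),
                  levels = c(levels(labels), "discarded"))
  names(final) <- names(labels)
  out <- list(final_label = final, mean_vote = mean_vote,
              discarded = names(labels)[!keep], features = features,
              aborted = FALSE)
  if (diagnostics) out$vote_matrix <- votes
  class(out) <- "RefinementResult"
  out
}

#' @export
print.RefinementResult <- function(x, ...) {
  if (x$aborted) {
    cat("RefinementResult: aborted; input labels returned\n")
  } else {
    tab <- table(x$final_label)
    cat("RefinementResult:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", length(x$features), "feature genes\n")
  }
  invisible(x)
}

#' Full supervised fine-tuning of a two-cluster split
#'
#' Orchestrates the five refinement steps: (i) differential expression
#' between the two input clusters ([wilcoxon_deg()]) to define the gene
#' space; (ii) hierarchical two-way first split on those genes
#' ([initial_split()]); (iii) cross-validated random-forest feature selection
#' ([rf_feature_select()]); (iv) vote-probability-guided label adjustment
#' ([refine_labels()]); (v) repeated-CV ambiguity filtering ([cv_filter()]).
#' Fully deterministic under the config seed. If no gene passes the DEG
#' filter the procedure aborts with a warning and returns the input labels
#' undiscarded.
#'
#' @param dataset a normalized [expression_dataset()].
#' @param labels initial two-cluster factor over cells.
#' @param config a [refinement_config()].
#' @param deg_fc_min fold-change threshold for the step-(i) DEG screen.
#' @param diagnostics keep the per-run vote matrix?
#' @return a `RefinementResult` (see [cv_filter()]); `aborted = TRUE` when the
#'   clusters are molecularly indistinguishable.
#' @export
fine_tune_clusters <- function(dataset, labels, config = refinement_config(),
                               deg_fc_min = 2, diagnostics = FALSE) {
  labels <- .check_two_classes(.cell_labels(dataset, labels))
  withr_seed(config$seed, function() {
    g1 <- names(labels)[labels == levels(labels)[1]]
    g2 <- names(labels)[labels == levels(labels)[2]]
    deg <- wilcoxon_deg(dataset, g1, g2, fc_min = deg_fc_min)
    deg_genes <- deg$gene[deg$retained]
    if (length(deg_genes) < 2) {
      warning("fewer than 2 DEGs between the clusters; refinement aborted")
      return(structure(list(final_label = labels,
                            mean_vote = setNames(rep(NA_real_, length(labels)),
                                                 names(labels)),
                            discarded = character(), features = character(),
                            aborted = TRUE),
                       class = "RefinementResult"))
    }
    sub <- subset_dataset(dataset, genes = deg_genes)
    split <- initial_split(sub)
    feats <- rf_feature_select(sub, split, config)
    features <- feats$selected
    if (length(features) < 2) features <- head(feats$ranking$gene, 2)
    adjusted <- refine_labels(sub, split, features, config)
    cv_filter(sub, adjusted, features, config, diagnostics = diagnostics)
  })
}
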