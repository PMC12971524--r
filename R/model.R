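## Training-set assembly, nested cross-validation with grid search,
## genome-wide scoring, benchmark evaluation, and candidate selection.
## The user-facing centerpiece is driver_model(), which wires the feature
## computation, degree-matched negative sampling, cross-validation and the
## final fit into one classed object.

#' Assemble a labeled training set with degree-matched negatives
#'
#' Negatives are drawn in `ratio` passes over the positive list, each pass
#' matching every positive's degree (widening by +/-1 up to
#' `max_tolerance`), excluding positives and all previously drawn
#' negatives. The default ratio of 19 gives 5% positive prevalence, the
#' baseline expectation used when reading precision-recall areas.
#'
#' @param graph igraph gene graph.
#' @param positives character vector of positive-class genes; members
#'   outside the graph are dropped with a logged count.
#' @param ratio negatives per positive (default 19).
#' @param max_tolerance degree-matching tolerance.
#' @param seed RNG seed.
#' @param positive_source provenance label for the positive list.
#' @return object of class `labeled_set`: list with `genes`, `labels`
#'   (1 = positive), and `provenance`.
#' @export
assemble_training <- function(graph, positives, ratio = 19, max_tolerance = 1,
                              seed = 1, positive_source = "positives") {
  stopifnot(ratio >= 1)
  positives <- unique(as.character(positives))
  in_graph <- intersect(positives, igraph::V(graph)$name)
  n_out <- length(positives) - length(in_graph)
  if (n_out > 0) dp_log("%d positive gene(s) absent from the graph were dropped", n_out)
  if (length(in_graph) == 0) stop("no positive genes present in the graph")
  negatives <- character(0)
  for (pass in seq_len(ratio)) {
    drawn <- tryCatch(
      sample_degree_matched(graph, targets = in_graph,
                            exclude = c(in_graph, negatives),
                            max_tolerance = max_tolerance,
                            seed = derive_seed(seed, pass)),
      error = function(e) {
        stop(sprintf(
          "negative pool exhausted at pass %d of %d (achieved ratio %d): %s",
          pass, ratio, pass - 1L, conditionMessage(e)))
      })
    negatives <- c(negatives, drawn)
  }
  structure(
    list(genes = c(in_graph, negatives),
         labels = c(rep(1L, length(in_graph)), rep(0L, length(negatives))),
         provenance = list(positive_source = positive_source, seed = seed,
                           ratio = ratio)),
    class = "labeled_set"
  )
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("<labeled_set> %d genes (%d positive, %d negative; prevalence %.4f)\n",
              length(x$genes), sum(x$labels == 1), sum(x$labels == 0),
              mean(x$labels)))
  invisible(x)
}

## Stratified fold assignment: within each class, shuffle then deal round-robin.
.stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

## Align a labeled set with a feature matrix; NA features imputed to 0
## (absence of proximity evidence) with a logged count.
.labeled_features <- function(features, labeled) {
  missing <- setdiff(labeled$genes, rownames(features))
  if (length(missing) > 0) {
    stop(sprintf("labeled gene(s) without feature rows: %s%s",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""))
  }
  X <- features[labeled$genes, , drop = FALSE]
  if (anyNA(X)) {
    dp_log("imputed %d missing feature value(s) to 0", sum(is.na(X)))
    X[is.na(X)] <- 0
  }
  X
}

## Inner grid selection: k-fold CV over the candidate configurations on the
## training data only; best mean AUROC wins, ties to the first-listed
## configuration.
.grid_select <- function(X, y, family, grid, inner_folds, seed) {
  configs <- .expand_grid(grid)
  if (length(configs) == 1) return(configs[[1]])
  fold <- .stratified_folds(y, inner_folds, derive_seed(seed, 77))
  mean_auc <- vapply(seq_along(configs), function(ci) {
    aucs <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2) return(NA_real_)
      h <- .fit_family(family, configs[[ci]], X[tr, , drop = FALSE], y[tr],
                       seed = derive_seed(seed, 1000 + ci * inner_folds + f))
      auroc(.predict_prob(h, X[!tr, , drop = FALSE]), y[!tr])
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  configs[[which.max(mean_auc)]]  # which.max takes the first maximum
}

#' Cross-validated performance of a classifier on proximity features
#'
#' Stratified `folds`-fold cross-validation with nested grid search:
#' hyperparameters are selected by inner cross-validation on each outer
#' training split only, so outer test labels never influence selection.
#' Reported AUROC and AUPRC are means over the outer folds.
#'
#' @param features feature matrix (genes x sets), e.g. from
#'   [build_feature_matrix()].
#' @param labeled a [assemble_training()] labeled set.
#' @param family classifier family (see [default_grid()]).
#' @param grid hyperparameter grid; default [default_grid()] for the
#'   family.
#' @param folds number of outer folds (default 5).
#' @param inner_folds folds for inner grid selection (default 3).
#' @param seed RNG seed.
#' @return object of class `metrics_record`: list with `auroc`, `auprc`,
#'   `fold_auroc`, `fold_auprc`, `prevalence`, `family`, and `cv_scores`
#'   (out-of-fold scores aligned with `labeled$genes`).
#' @export
cross_validate <- function(features, labeled, family = "extra_trees",
                           grid = NULL, folds = 5, inner_folds = 3, seed = 1) {
  stopifnot(inherits(labeled, "labeled_set"), folds >= 2)
  family <- match.arg(family, MODEL_FAMILIES)
  grid <- grid %||% default_grid(family)
  X <- .labeled_features(features, labeled)
  y <- labeled$labels
  fold <- .stratified_folds(y, folds, seed)
  if (any(vapply(seq_len(folds), function(f) length(unique(y[fold == f])) < 2, TRUE))) {
    stop("a fold contains a single class; reduce folds or add data")
  }
  fold_auroc <- numeric(folds)
  fold_auprc <- numeric(folds)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    best <- .grid_select(X[tr, , drop = FALSE], y[tr], family, grid,
                         inner_folds, derive_seed(seed, f))
    h <- .fit_family(family, best, X[tr, , drop = FALSE], y[tr],
                     seed = derive_seed(seed, 500 + f))
    p <- .predict_prob(h, X[!tr, , drop = FALSE])
    oof[!tr] <- p
    fold_auroc[f] <- auroc(p, y[!tr])
    fold_auprc[f] <- auprc(p, y[!tr])
  }
  structure(
    list(auroc = mean(fold_auroc), auprc = mean(fold_auprc),
         fold_auroc = fold_auroc, fold_auprc = fold_auprc,
         prevalence = mean(y), family = family,
         cv_scores = stats::setNames(oof, labeled$genes),
         cv_labels = stats::setNames(y, labeled$genes)),
    class = "metrics_record"
  )
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("<metrics_record> %s, %d-fold CV: AUROC %.3f, AUPRC %.3f (prevalence %.3f)\n",
              x$family, length(x$fold_auroc), x$auroc, x$auprc, x$prevalence))
  invisible(x)
}

#' Fit a classifier on the full labeled data
#'
#' Hyperparameters are grid-selected by internal cross-validation on the
#' labeled data, then the model is refit on all of it.
#'
#' @inheritParams cross_validate
#' @return a fitted classifier handle (class `dp_classifier`).
#' @export
fit_classifier <- function(features, labeled, family = "extra_trees",
                           grid = NULL, inner_folds = 3, seed = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  grid <- grid %||% default_grid(family)
  X <- .labeled_features(features, labeled)
  best <- .grid_select(X, labeled$labels, family, grid, inner_folds,
                       derive_seed(seed, 9))
  .fit_family(family, best, X, labeled$labels, seed = derive_seed(seed, 10))
}

#' Score every feature row with a fitted classifier
#'
#' @param model a `dp_classifier` handle or a [driver_model()] object.
#' @param features feature matrix whose columns match (by name and order)
#'   those the model was trained on; `NA` entries are imputed to 0.
#' @return data.frame of class `score_table` with columns `gene`, `score`,
#'   `rank`, ordered by deterministic rank (descending score, ties by
#'   ascending gene identifier).
#' @export
score_all <- function(model, features) {
  if (inherits(model, "driver_model")) model <- model$classifier
  X <- features
  if (anyNA(X)) {
    dp_log("imputed %d missing feature value(s) to 0 before scoring", sum(is.na(X)))
    X[is.na(X)] <- 0
  }
  p <- .predict_prob(model, X)
  ord <- order_scores(rownames(X), p)
  out <- data.frame(gene = rownames(X)[ord], score = p[ord],
                    rank = seq_along(p), stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Write / read a score table (TSV: gene, score, rank)
#'
#' @param scores a `score_table`.
#' @param path file path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("score_table", "data.frame")
  df
}

#' Consensus gold set across curated driver lists
#'
#' Genes appearing in at least `min_lists` of the supplied lists; with the
#' default of 2 this is the "at least two independent sources" consensus
#' used to define a benchmark-independent gold standard.
#'
#' @param lists named list of character vectors.
#' @param min_lists minimum number of lists (default 2).
#' @return character vector of consensus genes (sorted).
#' @export
build_gold_set <- function(lists, min_lists = 2) {
  stopifnot(length(lists) >= min_lists)
  counts <- table(unlist(lapply(lists, unique), use.names = FALSE))
  sort(names(counts)[counts >= min_lists])
}

#' Select the extreme candidates of a score table
#'
#' After removing `exclude` (known drivers and feature-set members,
#' typically), returns the first `n` genes by deterministic rank (the
#' high-scoring candidate list) and the last `n` (the low list). Default
#' `n = 2000`, the conventional top/bottom-2,000 candidate slices.
#'
#' @param scores a `score_table`.
#' @param exclude character vector of genes to remove before slicing.
#' @param n slice size.
#' @return list with `high` and `low` character vectors in rank order.
#' @export
select_extremes <- function(scores, exclude = character(0), n = 2000) {
  stopifnot(inherits(scores, "score_table"))
  kept <- scores$gene[!scores$gene %in% exclude]
  if (length(kept) < 2 * n) {
    stop(sprintf("only %d genes remain after exclusion; need at least %d",
                 length(kept), 2 * n))
  }
  list(high = kept[seq_len(n)],
       low = kept[seq(length(kept) - n + 1, length(kept))])
}

#' Evaluate a fitted model against a benchmark driver list
#'
#' AUROC over the benchmark positives (restricted to scored genes) and an
#' equal-size freshly drawn degree-matched negative set.
#'
#' @param model fitted classifier or [driver_model()] object.
#' @param features feature matrix covering the graph genes.
#' @param graph igraph gene graph (for degree matching).
#' @param benchmark character vector of benchmark positive genes.
#' @param exclude genes never used as negatives (e.g. training positives),
#'   in addition to the benchmark genes themselves.
#' @param max_tolerance,seed degree-matching controls.
#' @return list with `auroc`, `n_positive`, `n_negative`.
#' @export
evaluate_benchmark <- function(model, features, graph, benchmark,
                               exclude = character(0), max_tolerance = 1,
                               seed = 1) {
  pos <- intersect(unique(as.character(benchmark)), rownames(features))
  pos <- intersect(pos, igraph::V(graph)$name)
  if (length(pos) < 2) stop("fewer than 2 benchmark genes with feature rows")
  neg <- sample_degree_matched(graph, targets = pos,
                               exclude = c(pos, exclude),
                               max_tolerance = max_tolerance, seed = seed)
  st <- score_all(model, features[c(pos, neg), , drop = FALSE])
  sc <- stats::setNames(st$score, st$gene)
  genes <- c(pos, neg)
  list(auroc = auroc(sc[genes], c(rep(1L, length(pos)), rep(0L, length(neg)))),
       n_positive = length(pos), n_negative = length(neg))
}
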