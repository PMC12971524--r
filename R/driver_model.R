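## The user-facing model object: one fitting function wiring feature
## construction, degree-matched training assembly, nested cross-validation
## and the final genome-wide classifier, with the usual methods.

#' Fit a network-proximity driver-gene model
#'
#' The central fitting function. Given an interaction graph, an ordered
#' collection of process gene sets, and a list of known driver genes
#' (positives), it:
#' \enumerate{
#'   \item computes, for every gene, one proximity feature per set — the
#'     fraction of the set's network-resident members within hop distance
#'     `d` (default 2, the median pairwise network distance) of the gene;
#'   \item assembles a training set of the positives plus `ratio`
#'     degree-matched negatives per positive (default 19, i.e. 5%
#'     prevalence);
#'   \item estimates out-of-sample performance by stratified `folds`-fold
#'     cross-validation with nested grid search (AUROC / AUPRC);
#'   \item refits the selected configuration on all labeled genes.
#' }
#' The returned object scores any gene in the graph via [predict()].
#'
#' @param graph igraph gene graph (see [read_network()]).
#' @param collection a [gene_set_collection()]; its order fixes the feature
#'   columns.
#' @param positives character vector of known driver genes.
#' @param d inclusive distance threshold for the proximity features.
#' @param ratio negatives per positive.
#' @param family classifier family; default `"extra_trees"` (extremely
#'   randomized trees), the family that performs best on these features.
#' @param grid hyperparameter grid (default [default_grid()]).
#' @param folds outer cross-validation folds.
#' @param max_tolerance degree-matching tolerance for negative sampling.
#' @param seed RNG seed governing negative sampling, fold assignment and
#'   classifier randomness.
#' @param features optional precomputed feature matrix for all graph genes
#'   (rows must cover the graph nodes); computed when `NULL`.
#' @param cv set `FALSE` to skip cross-validation (fit only).
#' @return object of class `driver_model` with components `classifier`,
#'   `features`, `labeled`, `metrics` (a `metrics_record` or `NULL`),
#'   `config` (thresholds and seed) and `collection_names`.
#' @seealso [score_all()], [select_extremes()], [evaluate_benchmark()]
#' @examples
#' sim <- generate_synthetic(synth_config(n_genes = 400, n_drivers = 30,
#'                                        n_sets = 3, set_size = 25, seed = 1))
#' fit <- driver_model(sim$graph, sim$collection, sim$drivers,
#'                     ratio = 3, folds = 3,
#'                     grid = list(n_trees = 100), seed = 1)
#' fit
#' head(predict(fit))
#' @export
driver_model <- function(graph, collection, positives, d = 2, ratio = 19,
                         family = "extra_trees", grid = NULL, folds = 5,
                         max_tolerance = 1, seed = 1, features = NULL,
                         cv = TRUE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  family <- match.arg(family, MODEL_FAMILIES)
  if (is.null(features)) {
    features <- build_feature_matrix(graph, collection, d = d)
  }
  labeled <- assemble_training(graph, positives, ratio = ratio,
                               max_tolerance = max_tolerance,
                               seed = derive_seed(seed, 1))
  metrics <- NULL
  if (isTRUE(cv)) {
    metrics <- cross_validate(features, labeled, family = family, grid = grid,
                              folds = folds, seed = derive_seed(seed, 2))
  }
  classifier <- fit_classifier(features, labeled, family = family, grid = grid,
                               seed = derive_seed(seed, 3))
  structure(
    list(classifier = classifier,
         features = features,
         labeled = labeled,
         metrics = metrics,
         config = list(d = d, ratio = ratio, family = family, folds = folds,
                       max_tolerance = max_tolerance, seed = seed),
         collection_names = names(collection)),
    class = "driver_model"
  )
}

#' @export
print.driver_model <- function(x, ...) {
  cat(sprintf("<driver_model> %s on %d proximity features (d = %d)\n",
              x$config$family, length(x$collection_names), x$config$d))
  cat(sprintf("  training: %d positives + %d degree-matched negatives (ratio %d)\n",
              sum(x$labeled$labels == 1), sum(x$labeled$labels == 0),
              x$config$ratio))
  if (!is.null(x$metrics)) {
    cat(sprintf("  %d-fold CV: AUROC %.3f, AUPRC %.3f (baseline %.3f)\n",
                length(x$metrics$fold_auroc), x$metrics$auroc,
                x$metrics$auprc, x$metrics$prevalence))
  }
  invisible(x)
}

#' @export
summary.driver_model <- function(object, ...) {
  print(object)
  if (!is.null(object$metrics)) {
    cat("  per-fold AUROC:",
        paste(sprintf("%.3f", object$metrics$fold_auroc), collapse = ", "), "\n")
    cat("  per-fold AUPRC:",
        paste(sprintf("%.3f", object$metrics$fold_auprc), collapse = ", "), "\n")
  }
  cat("  selected hyperparameters:",
      paste(names(object$classifier$params),
            unlist(object$classifier$params), sep = "=", collapse = ", "), "\n")
  invisible(object)
}

#' Score genes with a fitted driver model
#'
#' @param object a [driver_model()].
#' @param newdata optional feature matrix (genes x sets, columns matching
#'   the training features); defaults to the full matrix the model was
#'   built on, i.e. genome-wide scoring.
#' @param ... unused.
#' @return a `score_table` (gene, score, rank).
#' @export
predict.driver_model <- function(object, newdata = NULL, ...) {
  score_all(object$classifier, newdata %||% object$features)
}

#' ROC curve of the cross-validated driver model
#'
#' Plots the pooled out-of-fold ROC curve from cross-validation.
#'
#' @param x a [driver_model()] fitted with `cv = TRUE`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.driver_model <- function(x, ...) {
  if (is.null(x$metrics)) stop("model was fitted with cv = FALSE; nothing to plot")
  s <- x$metrics$cv_scores
  l <- x$metrics$cv_labels
  ord <- order(-s)
  tpr <- cumsum(l[ord] == 1) / sum(l == 1)
  fpr <- cumsum(l[ord] == 0) / sum(l == 0)
  graphics::plot(c(0, fpr), c(0, tpr), type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("Out-of-fold ROC (AUROC %.3f)", x$metrics$auroc),
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Save / load a fitted driver model
#'
#' The bundle embeds the classifier family, selected hyperparameters, seed
#' and feature column names; [score_all()] refuses matrices whose columns
#' mismatch by name or order.
#'
#' @param model a [driver_model()].
#' @param path file path (RDS).
#' @export
save_driver_model <- function(model, path) {
  stopifnot(inherits(model, "driver_model"))
  saveRDS(list(format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_driver_model
#' @export
load_driver_model <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format_version, 1L)) {
    stop(sprintf("unsupported model file version: %s", bundle$format_version))
  }
  bundle$model
}
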