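## Classifier family abstraction. Each family is fit through a uniform
## interface: .fit_family(family, params, X, y, seed) returns a handle whose
## .predict_prob() gives P(class = 1) for new rows. Families mirror the
## standard scikit-style lineup: SVM (RBF), random forest, AdaBoost,
## gradient boosting, logistic regression, and extremely randomized trees.

MODEL_FAMILIES <- c("extra_trees", "random_forest", "adaboost",
                    "gradient_boosting", "logistic", "svm")

#' Default hyperparameter grid for a classifier family
#'
#' Deliberately small grids suitable for nested cross-validation at desk
#' scale: tree ensembles vary tree count, depth and leaf size; boosting
#' varies estimator count and learning rate; SVM and logistic vary the
#' inverse-regularization constant C.
#'
#' @param family one of `r paste(MODEL_FAMILIES, collapse = ", ")`.
#' @return named list mapping hyperparameter name to a vector of candidate
#'   values.
#' @export
default_grid <- function(family) {
  family <- match.arg(family, MODEL_FAMILIES)
  switch(family,
    extra_trees = ,
    random_forest = list(n_trees = c(100, 300), max_depth = c(0, 8),
                         min_leaf = c(1, 5)),
    gradient_boosting = ,
    adaboost = list(n_estimators = c(100, 300), learning_rate = c(0.1, 1.0)),
    svm = list(C = c(0.1, 1, 10)),
    logistic = list(C = c(0.1, 1, 10))
  )
}

## Expand a grid (named list of vectors) into a list of parameter sets,
## first-listed configuration first (grid-selection ties break toward it).
.expand_grid <- function(grid) {
  if (length(grid) == 0) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

.fit_family <- function(family, params, X, y, seed = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0, 1)))
  fitter <- switch(family,
    extra_trees = .fit_ranger_et,
    random_forest = .fit_ranger_rf,
    gradient_boosting = .fit_xgb,
    adaboost = .fit_adaboost,
    svm = .fit_svm,
    logistic = .fit_logistic
  )
  handle <- with_seed(seed, fitter(params, X, y))
  handle$family <- family
  handle$params <- params
  handle$feature_names <- colnames(X)
  class(handle) <- "dp_classifier"
  handle
}

.predict_prob <- function(handle, X) {
  stopifnot(inherits(handle, "dp_classifier"))
  if (!identical(colnames(X), handle$feature_names)) {
    stop("feature columns do not match the fitted model (name/order)")
  }
  p <- handle$predict(handle, X)
  pmin(1, pmax(0, as.numeric(p)))
}

.fit_ranger_et <- function(params, X, y) {
  fit <- ranger::ranger(
    x = X, y = factor(y, levels = c(0, 1)),
    num.trees = params$n_trees %||% 300,
    max.depth = params$max_depth %||% 0,
    min.node.size = params$min_leaf %||% 1,
    splitrule = "extratrees", num.random.splits = 1,
    replace = FALSE, sample.fraction = 1,
    probability = TRUE, num.threads = 1,
    seed = sample.int(2^30, 1)
  )
  list(fit = fit, predict = function(h, X) {
    stats::predict(h$fit, data = X, num.threads = 1)$predictions[, "1"]
  })
}

.fit_ranger_rf <- function(params, X, y) {
  fit <- ranger::ranger(
    x = X, y = factor(y, levels = c(0, 1)),
    num.trees = params$n_trees %||% 300,
    max.depth = params$max_depth %||% 0,
    min.node.size = params$min_leaf %||% 1,
    probability = TRUE, num.threads = 1,
    seed = sample.int(2^30, 1)
  )
  list(fit = fit, predict = function(h, X) {
    stats::predict(h$fit, data = X, num.threads = 1)$predictions[, "1"]
  })
}

.fit_xgb <- function(params, X, y) {
  fit <- xgboost::xgboost(
    X, factor(y, levels = c(0, 1)),
    nrounds = params$n_estimators %||% 100,
    learning_rate = params$learning_rate %||% 0.1,
    max_depth = 3,
    nthread = 1, verbosity = 0,
    seed = sample.int(2^30, 1)
  )
  list(fit = fit, predict = function(h, X) {
    stats::predict(h$fit, X, type = "response")
  })
}

## AdaBoost (SAMME) over depth-1 rpart stumps. Scores are mapped to [0, 1]
## through the logistic of the aggregated margin, giving a monotone
## probability-like output.
.fit_adaboost <- function(params, X, y) {
  M <- params$n_estimators %||% 100
  nu <- params$learning_rate %||% 0.1
  n <- nrow(X)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1, 1, -1)
  df <- data.frame(X, check.names = FALSE)
  df$.y <- factor(y, levels = c(0, 1))
  stumps <- vector("list", M)
  alphas <- numeric(M)
  m_used <- 0L
  for (m in seq_len(M)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w / mean(w),
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- ifelse(stats::predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- nu * 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    m_used <- m
    stumps[[m]] <- fit
    alphas[m] <- alpha
    if (err <= 1e-10) break
  }
  list(
    stumps = stumps[seq_len(m_used)], alphas = alphas[seq_len(m_used)],
    predict = function(h, X) {
      nd <- data.frame(X, check.names = FALSE)
      if (length(h$stumps) == 0) return(rep(0.5, nrow(X)))
      margin <- rep(0, nrow(X))
      for (m in seq_along(h$stumps)) {
        pr <- ifelse(stats::predict(h$stumps[[m]], nd, type = "class") == "1", 1, -1)
        margin <- margin + h$alphas[m] * pr
      }
      1 / (1 + exp(-2 * margin))
    }
  )
}

.fit_svm <- function(params, X, y) {
  fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                    kernel = "radial", cost = params$C %||% 1,
                    probability = TRUE, scale = TRUE)
  list(fit = fit, predict = function(h, X) {
    pr <- stats::predict(h$fit, X, probability = TRUE)
    attr(pr, "probabilities")[, "1"]
  })
}

## Ridge-penalized logistic regression; the C grid maps to the glmnet
## penalty as lambda = 1 / (C * n), so larger C means weaker regularization.
.fit_logistic <- function(params, X, y) {
  C <- params$C %||% 1
  lambda <- 1 / (C * nrow(X))
  fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 0, lambda = lambda, standardize = TRUE)
  list(fit = fit, lambda = lambda, predict = function(h, X) {
    as.numeric(stats::predict(h$fit, X, s = h$lambda, type = "response"))
  })
}
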