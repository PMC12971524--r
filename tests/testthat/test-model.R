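test_that("training assembly yields the exact prevalence, degree matching, and determinism", {
  sim <- small_sim(seed = 2)
  pos <- sim$drivers[1:10]
  lab <- assemble_training(sim$graph, pos, ratio = 19, max_tolerance = Inf,
                           seed = 3)
  expect_length(lab$genes, 200)
  expect_equal(mean(lab$labels), 0.05)  # prevalence = 1 / (1 + ratio)
  expect_false(anyDuplicated(lab$genes) > 0)
  expect_length(intersect(lab$genes[lab$labels == 1], lab$genes[lab$labels == 0]), 0)

  lab2 <- assemble_training(sim$graph, pos, ratio = 19, max_tolerance = Inf,
                            seed = 3)
  expect_identical(lab, lab2)

  ring <- graph_from_edges(c("A B", "B C", "C D", "D E", "E F", "F A",
                             "A D", "B E", "C F"))
  lab3 <- assemble_training(ring, c("A", "B"), ratio = 1, seed = 1)
  expect_true(all(igraph::degree(ring)[lab3$genes[lab3$labels == 0]] == 3))

  expect_error(assemble_training(ring, c("A", "B"), ratio = 5, seed = 1),
               "achieved ratio")
})

test_that("AUROC matches exhaustive pairwise comparison and handles ties and reversals", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  for (s in 1:40) {
    seeded(s, {
      n <- sample(10:200, 1)
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
      expect_equal(auroc(scores, labels), auroc_pairwise(scores, labels),
                   tolerance = 1e-12)
    })
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUPRC integrates the PR curve stepwise with the prevalence baseline", {
  # perfect ranking: area 1
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # all scores tied: single PR point at (recall 1, precision = prevalence)
  expect_equal(auprc(rep(0.3, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  # hand-computed small case: order 0.9(+), 0.7(-), 0.5(+)
  # points: (1/2, 1/1), (1/2, 1/2), (2/2, 2/3) -> 0.5*1 + 0.5*(2/3)
  expect_equal(auprc(c(0.9, 0.7, 0.5), c(1, 0, 1)), 0.5 + 0.5 * 2 / 3)
  expect_error(auprc(1:3, c(0, 0, 0)), "both classes")
})

test_that("DeLong test is symmetric, unit for identical scores, and matches pROC", {
  seeded(11, {
    n <- 150
    labels <- rep(c(1, 0), c(50, 100))
    base <- labels + rnorm(n)
    a <- base + rnorm(n, sd = 0.8)
    b <- 0.7 * base + rnorm(n, sd = 1.0)
    same <- delong_test(a, a, labels)
    expect_equal(same$delta_auc, 0)
    expect_equal(same$p, 1)
    r1 <- delong_test(a, b, labels)
    r2 <- delong_test(b, a, labels)
    expect_equal(r1$delta_auc, -r2$delta_auc)
    expect_equal(r1$p, r2$p)
    skip_if_not_installed("pROC")
    ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                          pROC::roc(labels, b, quiet = TRUE),
                          method = "delong")
    expect_equal(r1$p, as.numeric(ref$p.value), tolerance = 1e-8)
    expect_equal(r1$delta_auc,
                 as.numeric(ref$estimate[1] - ref$estimate[2]),
                 tolerance = 1e-10)
  })
})

test_that("cross-validation reports one metric per fold and flags degenerate folds", {
  sim <- small_sim(seed = 5)
  lab <- assemble_training(sim$graph, sim$drivers, ratio = 3,
                           max_tolerance = Inf, seed = 2)
  M <- build_feature_matrix(sim$graph, sim$collection, d = 2)
  met <- cross_validate(M, lab, family = "logistic", folds = 5, seed = 7)
  expect_length(met$fold_auroc, 5)
  expect_length(met$fold_auprc, 5)
  expect_equal(met$prevalence, 0.25)
  expect_gt(met$auroc, 0.7)  # planted signal is separable even linearly

  tiny <- lab
  tiny$genes <- lab$genes[c(1, 41:60)]
  tiny$labels <- lab$labels[c(1, 41:60)]
  expect_error(cross_validate(M, tiny, family = "logistic", folds = 3, seed = 1),
               "single class")
})

test_that("grid selection never sees outer-fold labels (nested-CV leakage canary)", {
  # with pure-noise features and random labels, honest nested CV stays near 0.5
  seeded(21, {
    n <- 240
    X <- matrix(runif(n * 6), n, dimnames = list(sprintf("g%03d", 1:n),
                                                 paste0("f", 1:6)))
    lab <- structure(list(genes = rownames(X), labels = rep(c(0L, 1L), n / 2),
                          provenance = list()), class = "labeled_set")
    met <- cross_validate(X, lab, family = "extra_trees",
                          grid = list(n_trees = 100, max_depth = c(0, 8)),
                          folds = 4, seed = 3)
    expect_gt(met$auroc, 0.3)
    expect_lt(met$auroc, 0.7)
  })
})

test_that("every classifier family separates a trivially separable problem", {
  seeded(31, {
    n <- 120
    y <- rep(c(1L, 0L), each = n / 2)
    X <- matrix(rep(y, 4) + runif(n * 4, 0, 0.05), n,
                dimnames = list(sprintf("g%03d", 1:n), paste0("f", 1:4)))
    lab <- structure(list(genes = rownames(X), labels = y, provenance = list()),
                     class = "labeled_set")
    for (fam in c("extra_trees", "random_forest", "adaboost",
                  "gradient_boosting", "logistic", "svm")) {
      h <- fit_classifier(X, lab, family = fam,
                          grid = lapply(default_grid(fam), `[`, 1), seed = 5)
      st <- score_all(h, X)
      sc <- stats::setNames(st$score, st$gene)
      expect_gt(min(sc[lab$genes[y == 1]]), max(sc[lab$genes[y == 0]]))
    }
  })
})

test_that("driver model defaults to extremely randomized trees and scores deterministically", {
  sim <- small_sim(seed = 6)
  fit <- driver_model(sim$graph, sim$collection, sim$drivers, ratio = 3,
                      folds = 3, grid = list(n_trees = 100),
                      max_tolerance = Inf, seed = 8)
  expect_identical(fit$config$family, "extra_trees")
  expect_identical(fit$classifier$family, "extra_trees")
  st <- predict(fit)
  expect_s3_class(st, "score_table")
  expect_true(all(st$score >= 0 & st$score <= 1))
  expect_identical(st$rank, seq_len(nrow(st)))

  # serialization round trip reproduces scores bit-identically
  p <- tempfile(fileext = ".rds")
  save_driver_model(fit, p)
  fit2 <- load_driver_model(p)
  expect_identical(predict(fit2), st)

  # refitting with the same seed reproduces the same scores
  fit3 <- driver_model(sim$graph, sim$collection, sim$drivers, ratio = 3,
                       folds = 3, grid = list(n_trees = 100),
                       max_tolerance = Inf, seed = 8)
  expect_identical(predict(fit3), st)

  # column mismatch is refused
  Mbad <- fit$features[, rev(colnames(fit$features))]
  expect_error(score_all(fit, Mbad), "columns do not match")
})

test_that("benchmark evaluation recovers planted drivers against fresh negatives", {
  sim <- small_sim(seed = 12)
  fit <- driver_model(sim$graph, sim$collection, sim$drivers[1:25], ratio = 3,
                      folds = 3, grid = list(n_trees = 100),
                      max_tolerance = Inf, seed = 2)
  held_out <- sim$drivers[26:40]
  res <- evaluate_benchmark(fit, fit$features, sim$graph, held_out,
                            exclude = fit$labeled$genes, max_tolerance = Inf,
                            seed = 4)
  expect_gt(res$auroc, 0.7)
  expect_equal(res$n_positive, 15)
  expect_equal(res$n_negative, 15)
})

test_that("gold-set consensus and extreme selection follow their counting rules", {
  expect_setequal(build_gold_set(list(l1 = c("A", "B"), l2 = c("B", "C"),
                                      l3 = "A"), 2), c("A", "B"))
  expect_setequal(build_gold_set(list(l1 = c("A", "B"), l2 = "C"), 1),
                  c("A", "B", "C"))
  for (s in 1:10) {
    lists <- seeded(s, lapply(1:5, function(i) sample(LETTERS, sample(5:15, 1))))
    got <- build_gold_set(lists, 2)
    counts <- table(unlist(lapply(lists, unique)))
    expect_setequal(got, names(counts)[counts >= 2])
  }

  st <- structure(
    data.frame(gene = sprintf("g%02d", 1:10), score = seq(1, 0.1, by = -0.1),
               rank = 1:10, stringsAsFactors = FALSE),
    class = c("score_table", "data.frame"))
  ext <- select_extremes(st, exclude = "g01", n = 2)
  expect_identical(ext$high, c("g02", "g03"))
  expect_identical(ext$low, c("g09", "g10"))
  expect_length(intersect(ext$high, ext$low), 0)
  expect_error(select_extremes(st, n = 6), "need at least")

  # tied scores resolve identically across runs
  st2 <- st
  st2$score <- rep(0.5, 10)
  ord <- order(-st2$score, st2$gene)
  st2 <- st2[ord, ]; st2$rank <- 1:10
  class(st2) <- c("score_table", "data.frame")
  expect_identical(select_extremes(st2, n = 3), select_extremes(st2, n = 3))
})
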