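test_that("cross-set distances enumerate ordered pairs, skip self-pairs, count disconnected", {
  g <- path_graph(c("A", "B", "C", "D"))
  expect_equal(sort(as.integer(cross_set_distances(g, "A", c("C", "D")))),
               c(2L, 3L))
  expect_equal(as.integer(cross_set_distances(g, "A", c("A", "B"))), 1L)

  g2 <- graph_from_edges(c("A B", "C D"))
  d <- cross_set_distances(g2, c("A"), c("B", "C"))
  expect_equal(as.integer(d), 1L)
  expect_equal(attr(d, "n_infinite"), 1L)
  expect_error(cross_set_distances(g2, "Q", "A"), "empty")
})

test_that("cross-set distance multisets equal the Floyd-Warshall oracle", {
  for (s in 1:15) {
    g <- random_test_graph(25, 0.12, seed = s)
    D <- floyd_warshall(g)
    verts <- igraph::V(g)$name
    x <- seeded(s, sample(verts, 5))
    y <- seeded(s + 50, sample(verts, 7))
    got <- sort(as.integer(cross_set_distances(g, x, y)))
    want <- c()
    for (a in x) for (b in y) {
      if (a != b && is.finite(D[a, b])) want <- c(want, D[a, b])
    }
    expect_equal(got, sort(as.integer(want)))
  }
})

test_that("rank-sum p-values match exact enumeration on small samples", {
  res <- ranksum_test(c(1, 1, 2), c(2, 3, 3), alternative = "less")
  expect_equal(res$p, ranksum_enum(c(1, 1, 2), c(2, 3, 3)), tolerance = 1e-12)
  for (s in 1:30) {
    seeded(s, {
      x <- sample(1:4, sample(3:6, 1), replace = TRUE)
      y <- sample(1:4, sample(3:6, 1), replace = TRUE)
      expect_equal(ranksum_test(x, y, "less")$p, ranksum_enum(x, y, "less"),
                   tolerance = 1e-12)
      expect_equal(ranksum_test(x, y, "greater")$p, ranksum_enum(x, y, "greater"),
                   tolerance = 1e-12)
    })
  }
})

test_that("large-sample rank-sum approximation tracks wilcox.test without continuity correction", {
  for (s in 1:10) {
    seeded(s, {
      x <- sample(1:6, 40, replace = TRUE)
      y <- sample(1:6, 35, replace = TRUE)
      got <- ranksum_test(x, y, "less")$p
      want <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "less", exact = FALSE,
                           correct = FALSE)$p.value)
      expect_equal(got, want, tolerance = 1e-9)
    })
  }
})

test_that("proximity test returns 0.5 under complete ties and finds planted proximity", {
  k <- graph_from_edges(utils::combn(LETTERS[1:8], 2, paste, collapse = " "))
  rec <- proximity_test(k, LETTERS[1:3], LETTERS[4:6], seed = 2)
  expect_equal(rec$rank_sum_p, 0.5)
  expect_equal(rec$log_fc_means, 0)

  # planted drivers are wired into every module; the background is drawn
  # outside the planted sets because at this scale only module members are
  # degree-comparable to the drivers
  sim <- small_sim(seed = 9)
  members <- unlist(lapply(sim$collection, `[[`, "members"))
  rec2 <- proximity_test(sim$graph, gene_set("drivers", sim$drivers),
                         sim$collection[[1]], max_tolerance = Inf, seed = 5,
                         exclude = c(sim$drivers, members))
  expect_lt(rec2$rank_sum_p, 0.05)
  expect_lt(rec2$log_fc_means, 0)
})

test_that("repeated-draw proximity testing averages over backgrounds deterministically", {
  sim <- small_sim(seed = 10)
  r1 <- proximity_test(sim$graph, sim$drivers[1:20], sim$collection[[2]],
                       max_tolerance = Inf, seed = 3, n_repeats = 3)
  r2 <- proximity_test(sim$graph, sim$drivers[1:20], sim$collection[[2]],
                       max_tolerance = Inf, seed = 3, n_repeats = 3)
  expect_identical(r1$rank_sum_p, r2$rank_sum_p)
  expect_identical(r1$log_fc_means, r2$log_fc_means)
  # three draws contribute roughly three backgrounds' worth of pairs (self-
  # pairs and disconnected pairs may be dropped from individual draws)
  expect_gt(r1$n_pairs_background, 2 * r1$n_pairs_actual)
})

test_that("proximity fractions follow the self-exclusion and denominator rules", {
  g <- path_graph(c("A", "B", "C", "D", "E"))
  expect_equal(proximity_fraction(g, "C", c("A", "E"), d = 2), 1.0)
  # A excluded from its own set; B at distance 1 in, E at distance 4 out
  expect_equal(proximity_fraction(g, "A", c("A", "B", "E"), d = 2), 0.5)
  expect_message(
    expect_identical(proximity_fraction(g, "A", c("A"), d = 2), NA_real_),
    "undefined")
  expect_error(proximity_fraction(g, "Q", "A"), "not in graph")
})

test_that("proximity fractions equal brute-force counts and grow with the threshold", {
  for (s in 1:10) {
    g <- random_test_graph(40, 0.08, seed = s)
    verts <- igraph::V(g)$name
    set <- seeded(s, sample(verts, 8))
    ggene <- verts[s]
    prev <- 0
    for (d in 1:4) {
      got <- proximity_fraction(g, ggene, set, d = d)
      dist <- shortest_distances(g, ggene)
      members <- setdiff(set, ggene)
      want <- sum(!is.na(dist[members]) & dist[members] <= d) / length(members)
      expect_equal(got, want)
      expect_gte(got, prev)  # monotone non-decreasing in d
      prev <- got
    }
  }
})

test_that("feature matrix matches per-pair recomputation and ignores input ordering", {
  sim <- generate_synthetic(synth_config(n_genes = 200, p_bg = 0.01, n_sets = 3,
                                         set_size = 15, n_drivers = 15,
                                         p_signal = 0.2, seed = 4))
  genes <- igraph::V(sim$graph)$name[1:40]
  M <- build_feature_matrix(sim$graph, sim$collection, genes = genes, d = 2)
  expect_identical(colnames(M), names(sim$collection))
  expect_identical(rownames(M), genes)
  for (i in seq(1, 40, by = 7)) {
    for (nm in names(sim$collection)) {
      expect_equal(M[i, nm],
                   proximity_fraction(sim$graph, genes[i],
                                      sim$collection[[nm]], d = 2))
    }
  }
  expect_true(all(M >= 0 & M <= 1, na.rm = TRUE))

  # invariance to set-member order and edge-file line order
  shuffled <- gene_set_collection(lapply(sim$collection, function(s) {
    gene_set(s$name, rev(s$members), s$process, s$direction)
  }))
  expect_identical(build_feature_matrix(sim$graph, shuffled, genes = genes, d = 2), M)

  p <- tempfile(fileext = ".tsv")
  uni <- tempfile()
  writeLines(igraph::V(sim$graph)$name, uni)
  write_network(sim$graph, p)
  lines <- readLines(p)
  writeLines(c(lines[1], rev(lines[-1])), p)
  g2 <- read_network(p, min_confidence = 0, universe_path = uni)
  expect_identical(build_feature_matrix(g2, sim$collection, genes = genes, d = 2), M)
})

test_that("nine-set collections give nine feature columns", {
  sim <- generate_synthetic(synth_config(n_genes = 300, n_sets = 9, set_size = 10,
                                         n_drivers = 20, seed = 6))
  M <- build_feature_matrix(sim$graph, sim$collection,
                            genes = igraph::V(sim$graph)$name[1:10], d = 2)
  expect_equal(ncol(M), 9)
})
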