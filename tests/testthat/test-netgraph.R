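test_that("read_network filters by confidence, dedups reversed lines, drops self-loops", {
  p <- write_edge_tsv(c("A\tB\t700", "B\tC\t500", "A\tC\t300"))
  g <- read_network(p, min_confidence = 400)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 2)
  expect_setequal(paste(pmin(el$from, el$to), pmax(el$from, el$to)),
                  c("A B", "B C"))

  p2 <- write_edge_tsv(c("A\tB\t700", "B\tA\t650"))
  g2 <- read_network(p2, min_confidence = 0)
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::E(g2)$confidence, 700)

  p3 <- write_edge_tsv(c("A\tA\t900", "B\tC\t800"))
  expect_message(g3 <- read_network(p3, min_confidence = 0), "self-loop")
  expect_false("A" %in% igraph::V(g3)$name)
})

test_that("read_network detects headers, honors a node universe, rejects bad scores", {
  p <- write_edge_tsv(c("A\tB\t700"), header = TRUE)
  g <- read_network(p, min_confidence = 400)
  expect_equal(igraph::ecount(g), 1)

  uni <- tempfile()
  writeLines(c("A", "B", "Z"), uni)
  g2 <- read_network(p, min_confidence = 400, universe_path = uni)
  expect_true("Z" %in% igraph::V(g2)$name)
  expect_equal(igraph::degree(g2)[["Z"]], 0)

  bad <- write_edge_tsv(c("A\tB\t700", "B\tC\txyz"))
  expect_error(read_network(bad), "line 2")
  expect_error(read_network(tempfile()), "cannot read")
})

test_that("network write/read round trip is the identity", {
  g <- random_test_graph(30, 0.15, seed = 5)
  # isolated vertices are not representable in an edge list without a
  # universe file, so compare on the edge-bearing subgraph
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  p <- tempfile(fileext = ".tsv")
  write_network(g, p)
  g2 <- read_network(p, min_confidence = 0)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  canon <- function(gg) {
    el <- igraph::as_data_frame(gg)
    sort(paste(pmin(el$from, el$to), pmax(el$from, el$to), el$confidence))
  }
  expect_identical(canon(g2), canon(g))
})

test_that("shortest_distances matches hand-computed paths and omits unreachable genes", {
  g <- path_graph(c("A", "B", "C"))
  expect_equal(shortest_distances(g, "A"), c(A = 0L, B = 1L, C = 2L))
  expect_equal(shortest_distances(g, "A", cutoff = 1), c(A = 0L, B = 1L))

  g2 <- graph_from_edges(c("A B", "C D"))
  d <- shortest_distances(g2, "A")
  expect_false(any(c("C", "D") %in% names(d)))
  expect_error(shortest_distances(g2, "Q"), "unknown source")
})

test_that("shortest_distances agrees exactly with a Floyd-Warshall oracle on seeded graphs", {
  for (s in 1:25) {
    n <- 10 + (s %% 4) * 10
    g <- random_test_graph(n, 0.12, seed = s)
    D <- floyd_warshall(g)
    for (src in igraph::V(g)$name[c(1, n %/% 2)]) {
      got <- shortest_distances(g, src)
      row <- D[src, ]
      want <- row[is.finite(row)]
      expect_equal(as.numeric(got[sort(names(got))]),
                   as.numeric(want[sort(names(want))]))
      expect_identical(sort(names(got)), sort(names(want)))
    }
  }
})

test_that("median pair distance is exact on closed forms and seed-independent when exhaustive", {
  k5 <- graph_from_edges(c("A B", "A C", "A D", "A E", "B C", "B D", "B E",
                           "C D", "C E", "D E"))
  expect_equal(estimate_median_pair_distance(k5, 100, seed = 3), 1L)
  # path with 5 nodes: pair distances {1,1,1,1,2,2,2,3,3,4}, lower median 2
  p5 <- path_graph(c("A", "B", "C", "D", "E"))
  expect_equal(estimate_median_pair_distance(p5, 10, seed = 1), 2L)
  expect_equal(estimate_median_pair_distance(p5, 10, seed = 99), 2L)
})

test_that("sampled median estimates match the exhaustive value on a larger graph", {
  g <- random_test_graph(120, 0.05, seed = 8)
  exact <- estimate_median_pair_distance(g, n_pairs = 10^6, seed = 1)
  sampled <- estimate_median_pair_distance(g, n_pairs = 500, seed = 2)
  expect_lte(abs(sampled - exact), 1)
})

test_that("degree-matched sampling respects degree bands, exclusions, and seeds", {
  # 3-regular graph: cycle with chords
  ring <- graph_from_edges(c("A B", "B C", "C D", "D E", "E F", "F A",
                             "A D", "B E", "C F"))
  res <- sample_degree_matched(ring, targets = c("A", "B"),
                               exclude = c("A", "B"), seed = 4)
  expect_length(res, 2)
  expect_false(any(res %in% c("A", "B")))
  expect_true(all(igraph::degree(ring)[res] == 3))
  expect_false(res[1] == res[2])

  star <- graph_from_edges(c("H A", "H B", "H C", "H D"))
  expect_error(sample_degree_matched(star, "H", max_tolerance = 1, seed = 1),
               "degree 4")

  g <- random_test_graph(80, 0.1, seed = 11)
  deg <- igraph::degree(g)
  targets <- igraph::V(g)$name[1:10]
  for (s in 1:20) {
    m <- sample_degree_matched(g, targets, exclude = targets,
                               max_tolerance = 1, seed = s)
    expect_true(all(abs(deg[m] - deg[targets]) <= 1))
    expect_false(any(m %in% targets))
    expect_false(anyDuplicated(m) > 0)
  }
  expect_identical(
    sample_degree_matched(g, targets, exclude = targets, seed = 7),
    sample_degree_matched(g, targets, exclude = targets, seed = 7)
  )
})
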