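# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive implementations kept separate from the package's code
# paths.

# All-pairs shortest hop distances by Floyd-Warshall on an adjacency matrix.
# Returns a symmetric matrix with Inf for disconnected pairs.
floyd_warshall <- function(graph) {
  verts <- igraph::V(graph)$name
  n <- length(verts)
  D <- matrix(Inf, n, n, dimnames = list(verts, verts))
  diag(D) <- 0
  el <- igraph::as_edgelist(graph)
  if (nrow(el) > 0) {
    D[cbind(el[, 1], el[, 2])] <- 1
    D[cbind(el[, 2], el[, 1])] <- 1
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Evaluate under a fixed seed without clobbering the session RNG stream.
seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Seeded Erdos-Renyi test graph with gene-style vertex names.
random_test_graph <- function(n, p, seed) {
  g <- seeded(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("g%03d", seq_len(n))
  igraph::E(g)$confidence <- 500L
  g
}

# Textbook Benjamini-Hochberg: p(i) * n / i at ascending ranks, cumulative
# minimum from the largest rank, capped at 1, restored to input order.
bh_textbook <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Exact hypergeometric upper tail by direct combinatorial sums.
fisher_tail_enum <- function(k, size_a, size_b, N) {
  k_max <- min(size_a, size_b)
  if (k > k_max) return(0)
  sum(vapply(k:k_max, function(i) {
    choose(size_a, i) * choose(N - size_a, size_b - i) / choose(N, size_b)
  }, 0))
}

# Exact one-sided rank-sum p-value by enumerating every assignment of the
# pooled ranks to the first sample.
ranksum_enum <- function(x, y, alternative = "less") {
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)])
  sums <- colSums(matrix(r[utils::combn(length(r), length(x))],
                         nrow = length(x)))
  switch(alternative,
         less = mean(sums <= W),
         greater = mean(sums >= W))
}

# AUROC by exhaustive comparison of every positive-negative pair.
auroc_pairwise <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Two-sided p-value for an AUC difference from a stratified paired
# bootstrap: resample positives and negatives (with replacement) jointly
# for both score vectors and read the tail mass of the delta distribution.
delong_bootstrap_p <- function(scores_a, scores_b, labels, n_rep = 10000,
                               seed = 1) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  seeded(seed, {
    deltas <- vapply(seq_len(n_rep), function(r) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      l <- labels[idx]
      auroc(scores_a[idx], l) - auroc(scores_b[idx], l)
    }, 0)
    2 * min(mean(deltas <= 0), mean(deltas >= 0))
  })
}
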