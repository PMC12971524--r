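## Set-to-set shortest-path distance distributions, degree-controlled
## proximity testing, and the per-gene proximity fractions that serve as
## classifier features.

#' Pairwise shortest-path distances between two gene sets
#'
#' One entry per ordered pair (a in x, b in y, a != b) with a finite hop
#' distance. Self-pairs are skipped; pairs in different components are
#' counted but not included. Set members absent from the graph are dropped
#' with a logged count.
#'
#' @param graph igraph gene graph.
#' @param x,y character vectors (or `gene_set`s) of genes.
#' @return integer vector of distances, with attribute `n_infinite` (count
#'   of disconnected pairs).
#' @export
cross_set_distances <- function(graph, x, y) {
  if (inherits(x, "gene_set")) x <- x$members
  if (inherits(y, "gene_set")) y <- y$members
  verts <- igraph::V(graph)$name
  x0 <- unique(as.character(x)); y0 <- unique(as.character(y))
  x <- intersect(x0, verts); y <- intersect(y0, verts)
  n_drop <- (length(x0) - length(x)) + (length(y0) - length(y))
  if (n_drop > 0) dp_log("%d set member(s) absent from the graph were dropped", n_drop)
  if (length(x) == 0 || length(y) == 0) {
    stop("a gene set is empty after intersecting with the graph nodes")
  }
  dm <- igraph::distances(graph, v = x, to = y, weights = NA)
  ## drop self-pairs (a == b)
  common <- intersect(x, y)
  if (length(common) > 0) {
    dm[cbind(match(common, rownames(dm)), match(common, colnames(dm)))] <- NA
  }
  vals <- as.vector(dm)
  vals <- vals[!is.na(vals)]
  n_inf <- sum(is.infinite(vals))
  out <- as.integer(vals[is.finite(vals)])
  attr(out, "n_infinite") <- n_inf
  out
}

#' Wilcoxon rank-sum test (one-sided, tie-aware)
#'
#' Tests whether values in `x` are stochastically smaller (`"less"`, the
#' default), larger, or different from values in `y`. When both samples have
#' at most `exact_max` observations the p-value is computed by exact
#' enumeration of all rank assignments (valid under ties); otherwise a
#' tie-corrected normal approximation to the rank-sum statistic is used.
#' When the rank-sum variance is zero (all pooled values tied) the one-sided
#' p-value is 0.5 by convention.
#'
#' @param x,y numeric vectors.
#' @param alternative `"less"`, `"greater"` or `"two.sided"`.
#' @param exact_max largest per-sample size for exact enumeration.
#' @return list with `statistic` (rank sum of `x`) and `p`.
#' @export
ranksum_test <- function(x, y, alternative = c("less", "greater", "two.sided"),
                         exact_max = 8) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need at least 2 observations per sample")
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(nx)])
  if (nx <= exact_max && ny <= exact_max) {
    combs <- utils::combn(nx + ny, nx)
    sums <- colSums(matrix(r[combs], nrow = nx))
    p_le <- mean(sums <= W)
    p_ge <- mean(sums >= W)
    p <- switch(alternative,
                less = p_le,
                greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    return(list(statistic = W, p = p))
  }
  N <- nx + ny
  mu <- nx * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    p <- if (alternative == "two.sided") 1 else 0.5
    return(list(statistic = W, p = p))
  }
  z <- (W - mu) / sqrt(sigma2)
  p <- switch(alternative,
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(statistic = W, p = p)
}

#' Degree-controlled proximity test between two gene sets
#'
#' Tests whether genes in `x` are closer to genes in `y` than a
#' degree-matched background set is: a control set `x'` is drawn by
#' [sample_degree_matched()] (one control per member of `x`, excluding `x`),
#' and the distance distributions dist(x, y) and dist(x', y) are compared
#' with a one-sided Wilcoxon rank-sum test (alternative: actual distances
#' stochastically smaller). The effect summary is
#' `log2(mean(dist(x, y)) / mean(dist(x', y)))`, negative when `x` is more
#' proximal than its degree-matched background; means are over finite
#' distances only. With `n_repeats > 1` the background draw is repeated and
#' the mean p-value and mean log fold-change are reported for stability.
#'
#' @param graph igraph gene graph.
#' @param x,y character vectors (or `gene_set`s); names are picked up from
#'   `gene_set` inputs.
#' @param max_tolerance degree-matching tolerance (see
#'   [sample_degree_matched()]).
#' @param seed RNG seed for the background draw(s).
#' @param n_repeats number of background draws to average over.
#' @param exclude genes the background may never contain; defaults to `x`
#'   itself. Supplying a wider set (e.g. the union of all process-set
#'   members) keeps other annotated sets out of the null when the gene
#'   universe is small relative to the sets, where a degree-matched draw
#'   would otherwise be dominated by them.
#' @return object of class `proximity_record`: a list with `set_x`, `set_y`,
#'   `n_pairs_actual`, `n_pairs_background`, `rank_sum_p`, `log_fc_means`,
#'   `n_infinite_dropped`.
#' @export
proximity_test <- function(graph, x, y, max_tolerance = 1, seed = 1,
                           n_repeats = 1, exclude = NULL) {
  name_x <- if (inherits(x, "gene_set")) x$name else "x"
  name_y <- if (inherits(y, "gene_set")) y$name else "y"
  if (inherits(x, "gene_set")) x <- x$members
  if (inherits(y, "gene_set")) y <- y$members
  x <- intersect(unique(as.character(x)), igraph::V(graph)$name)
  exclude <- unique(c(x, as.character(exclude %||% character(0))))
  d_actual <- cross_set_distances(graph, x, y)
  if (length(d_actual) < 2) stop("fewer than 2 finite actual distances")
  ps <- numeric(n_repeats)
  lfcs <- numeric(n_repeats)
  n_bg <- 0L
  n_inf_bg <- 0L
  for (r in seq_len(n_repeats)) {
    bg <- sample_degree_matched(graph, targets = x, exclude = exclude,
                                max_tolerance = max_tolerance,
                                seed = derive_seed(seed, r))
    d_bg <- cross_set_distances(graph, bg, y)
    if (length(d_bg) < 2) stop("fewer than 2 finite background distances")
    ps[r] <- ranksum_test(d_actual, d_bg, alternative = "less")$p
    lfcs[r] <- log2(mean(d_actual) / mean(d_bg))
    n_bg <- n_bg + length(d_bg)
    n_inf_bg <- n_inf_bg + attr(d_bg, "n_infinite")
  }
  structure(
    list(set_x = name_x, set_y = name_y,
         n_pairs_actual = length(d_actual),
         n_pairs_background = n_bg,
         rank_sum_p = mean(ps),
         log_fc_means = mean(lfcs),
         n_infinite_dropped = attr(d_actual, "n_infinite") + n_inf_bg),
    class = "proximity_record"
  )
}

#' @export
print.proximity_record <- function(x, ...) {
  cat(sprintf("<proximity_record> %s vs %s: p = %.3g, log2 FC of mean distances = %.3f\n",
              x$set_x, x$set_y, x$rank_sum_p, x$log_fc_means))
  cat(sprintf("  pairs: %d actual, %d background; %d disconnected pair(s) dropped\n",
              x$n_pairs_actual, x$n_pairs_background, x$n_infinite_dropped))
  invisible(x)
}

#' Proximity fraction of a gene to a gene set
#'
#' The fraction of network-resident members of `s` (excluding `g` itself)
#' that lie within hop distance `d` of gene `g`. Unreachable members count
#' only in the denominator. The gene's own membership is excluded so that a
#' gene's feature never encodes its own set membership. Returns `NA` (with a
#' log line) when `s` has no network-resident members other than `g`.
#'
#' @param graph igraph gene graph.
#' @param g a gene (graph node).
#' @param s character vector (or `gene_set`) of member genes.
#' @param d inclusive distance threshold; default 2, the median pairwise
#'   distance between random genes in genome-scale interaction networks.
#' @return real in \[0, 1\], or `NA_real_` when undefined.
#' @export
proximity_fraction <- function(graph, g, s, d = 2) {
  stopifnot(d >= 1)
  if (inherits(s, "gene_set")) s <- s$members
  if (!g %in% igraph::V(graph)$name) stop(sprintf("gene '%s' not in graph", g))
  members <- setdiff(intersect(unique(as.character(s)), igraph::V(graph)$name), g)
  if (length(members) == 0) {
    dp_log("set has no network-resident members besides '%s'; fraction undefined", g,
           level = "WARN")
    return(NA_real_)
  }
  near <- igraph::ego(graph, order = d, nodes = g)[[1]]$name
  sum(members %in% near) / length(members)
}

#' Build the proximity feature matrix
#'
#' One row per gene, one column per gene set in collection order; entries
#' are [proximity_fraction()] values. Rows are computed with a single
#' depth-limited traversal per gene, reused across all columns.
#'
#' @param graph igraph gene graph.
#' @param collection a [gene_set_collection()] (column order = collection
#'   order).
#' @param genes character vector of genes (rows); default all graph nodes.
#' @param d inclusive distance threshold (default 2).
#' @return numeric matrix with `genes` as rownames and set names as
#'   colnames; entries in \[0, 1\], `NA` where a fraction is undefined.
#' @export
build_feature_matrix <- function(graph, collection, genes = NULL, d = 2) {
  stopifnot(inherits(collection, "gene_set_collection"), d >= 1)
  verts <- igraph::V(graph)$name
  genes <- if (is.null(genes)) verts else as.character(genes)
  missing <- setdiff(genes, verts)
  if (length(missing) > 0) {
    stop(sprintf("gene(s) not in graph: %s%s",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""))
  }
  set_members <- lapply(collection, function(s) intersect(s$members, verts))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(collection),
                dimnames = list(genes, names(collection)))
  hoods <- igraph::ego(graph, order = d, nodes = genes)
  for (i in seq_along(genes)) {
    near <- hoods[[i]]$name
    g <- genes[i]
    for (j in seq_along(set_members)) {
      members <- setdiff(set_members[[j]], g)
      if (length(members) == 0) next  # stays NA
      mat[i, j] <- sum(members %in% near) / length(members)
    }
  }
  if (anyNA(mat)) {
    dp_log("%d feature entr(ies) undefined (no network-resident set members)",
           sum(is.na(mat)), level = "WARN")
  }
  mat
}

#' Write a feature matrix to TSV
#'
#' @param mat matrix from [build_feature_matrix()].
#' @param path output path.
#' @export
write_feature_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
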