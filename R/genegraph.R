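## Interaction-network container and primitives: reading STRING-style edge
## lists, unit-length shortest paths, degree indexing, and degree-matched
## sampling. The graph is an igraph object (undirected, simple) with a
## `confidence` edge attribute holding the integer combined score (0-1000).

#' Construct a gene interaction graph
#'
#' Builds an undirected simple graph of gene symbols from an edge table.
#' Self-loops are dropped and duplicate/reversed edges are collapsed keeping
#' the maximum confidence, mirroring how interaction-database dumps list both
#' orientations of each pair.
#'
#' @param edges data.frame with columns `from`, `to`, `confidence`
#'   (integer 0-1000).
#' @param nodes optional character vector of the node universe. Nodes without
#'   edges are kept as isolated vertices only when this is supplied.
#' @return an [igraph::igraph] object with vertex `name` and edge
#'   `confidence` attributes.
#' @export
gene_graph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "confidence") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  conf <- as.integer(edges$confidence)
  if (any(!is.finite(conf)) || any(conf < 0) || any(conf > 1000)) {
    stop("edge confidences must be integers in [0, 1000]")
  }
  keep <- from != to
  n_loops <- sum(!keep)
  if (n_loops > 0) {
    dp_log("dropped %d self-loop edge line(s)", n_loops, level = "WARN")
  }
  from <- from[keep]; to <- to[keep]; conf <- conf[keep]
  ## canonical orientation then max-confidence dedup
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    conf <- as.integer(tapply(conf, key, max)[unique(key)])
    first <- !duplicated(key)
    a <- a[first]; b <- b[first]
  }
  verts <- if (is.null(nodes)) sort(unique(c(a, b))) else sort(unique(as.character(nodes)))
  missing_ep <- setdiff(c(a, b), verts)
  if (length(missing_ep) > 0) {
    verts <- sort(unique(c(verts, missing_ep)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, confidence = conf, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
  g
}

#' Read a weighted interaction network from a TSV edge list
#'
#' Reads a STRING-dialect edge list (two identifier columns plus an integer
#' combined score 0-1000, whitespace or tab separated; gzip transparently
#' supported) and keeps edges at or above a confidence cutoff. The default
#' cutoff of 400 is the conventional "medium confidence" threshold for
#' STRING combined scores. A header line is auto-detected by a non-numeric
#' third field. Duplicate and reversed lines collapse to one edge keeping the
#' maximum confidence; self-loops are dropped with a logged count. Nodes
#' whose every edge is filtered out are retained only if `universe_path`
#' supplies an explicit node universe (one gene per line); otherwise they are
#' dropped.
#'
#' @param path path to the edge-list file (optionally gzipped).
#' @param min_confidence integer in \[0, 1000\]; edges with lower combined
#'   score are discarded. Default 400 (medium confidence).
#' @param universe_path optional path to a node-universe file, one gene per
#'   line.
#' @return an igraph gene graph (see [gene_graph()]).
#' @export
read_network <- function(path, min_confidence = 400, universe_path = NULL) {
  stopifnot(length(min_confidence) == 1L, min_confidence >= 0, min_confidence <= 1000)
  lines <- tryCatch(suppressWarnings(readLines(path)), error = function(e) {
    stop(sprintf("cannot read network file '%s': %s", path, conditionMessage(e)))
  })
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("network file '%s' is empty", path))
  fields <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0) {
    stop(sprintf("malformed network line %d: fewer than 3 fields", bad[1]))
  }
  third <- vapply(fields, `[[`, "", 3L)
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(third[1])))) {
    start <- 2L  # header detected
    if (length(lines) < 2) stop("network file has a header but no data lines")
  }
  idx <- seq(start, length(lines))
  score_chr <- third[idx]
  score <- suppressWarnings(as.numeric(score_chr))
  if (anyNA(score) || any(score != floor(score))) {
    line_no <- idx[which(is.na(score) | score != floor(score))[1]]
    stop(sprintf("malformed network line %d: non-integer score '%s'",
                 line_no, score_chr[which(is.na(score) | score != floor(score))[1]]))
  }
  from <- vapply(fields[idx], `[[`, "", 1L)
  to <- vapply(fields[idx], `[[`, "", 2L)
  keep <- score >= min_confidence
  universe <- NULL
  if (!is.null(universe_path)) {
    universe <- trimws(readLines(universe_path))
    universe <- universe[nzchar(universe)]
  }
  gene_graph(
    data.frame(from = from[keep], to = to[keep], confidence = as.integer(score[keep]),
               stringsAsFactors = FALSE),
    nodes = universe
  )
}

#' Write a gene graph back to an edge-list TSV
#'
#' @param graph igraph gene graph.
#' @param path output path.
#' @export
write_network <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  a <- pmin(el$from, el$to)
  b <- pmax(el$from, el$to)
  df <- data.frame(protein1 = a, protein2 = b, combined_score = el$confidence,
                   stringsAsFactors = FALSE)
  df <- df[order(df$protein1, df$protein2, method = "radix"), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Unit-length shortest-path distances from one gene
#'
#' Hop distances from `source` to every reachable gene by breadth-first
#' traversal; edge confidences are not used as weights, so the result is
#' identical to unit-weight Dijkstra. Unreachable genes are absent from the
#' returned mapping.
#'
#' @param graph igraph gene graph.
#' @param source gene identifier; must be a node.
#' @param cutoff optional integer; restrict the mapping to distances
#'   `<= cutoff`.
#' @return named integer vector of hop distances (includes `source` at 0).
#' @export
shortest_distances <- function(graph, source, cutoff = NULL) {
  if (!source %in% igraph::V(graph)$name) {
    stop(sprintf("unknown source gene '%s'", source))
  }
  d <- igraph::distances(graph, v = source, weights = NA)[1, ]
  d <- d[is.finite(d)]
  if (!is.null(cutoff)) d <- d[d <= cutoff]
  out <- as.integer(d)
  names(out) <- names(d)
  out
}

#' Estimate the median pairwise shortest-path distance
#'
#' Median hop distance between connected node pairs. When the number of
#' distinct pairs is at most `n_pairs` the median is exact over all connected
#' pairs; otherwise `n_pairs` distinct pairs are sampled uniformly (seeded),
#' disconnected pairs being discarded and resampled up to a retry bound. The
#' median of an even-length sample is the lower middle value, keeping the
#' result integral. This statistic motivates the package default distance
#' threshold `d = 2`, the median pairwise distance in genome-scale
#' interaction networks at medium confidence.
#'
#' @param graph igraph gene graph with at least 2 nodes.
#' @param n_pairs number of pairs to sample.
#' @param seed RNG seed for pair sampling.
#' @param max_retries resampling rounds allowed when sampled pairs are
#'   disconnected.
#' @return integer median distance.
#' @export
estimate_median_pair_distance <- function(graph, n_pairs = 100000, seed = 1,
                                          max_retries = 10) {
  n <- igraph::vcount(graph)
  if (n < 2) stop("graph must have at least 2 nodes")
  total_pairs <- n * (n - 1) / 2
  lower_median <- function(x) {
    s <- sort(x)
    s[[floor((length(s) + 1) / 2)]]
  }
  if (total_pairs <= n_pairs) {
    dm <- igraph::distances(graph, weights = NA)
    vals <- dm[upper.tri(dm)]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) stop("no connected node pair found")
    return(as.integer(lower_median(vals)))
  }
  verts <- igraph::V(graph)$name
  with_seed(seed, {
    collected <- integer(0)
    for (round in seq_len(max_retries)) {
      need <- n_pairs - length(collected)
      if (need <= 0) break
      i <- sample.int(n, need, replace = TRUE)
      j <- sample.int(n - 1, need, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)  # uniform over distinct pairs
      src <- unique(verts[i])
      dm <- igraph::distances(graph, v = src, to = verts[unique(j)], weights = NA)
      d <- dm[cbind(match(verts[i], rownames(dm)), match(verts[j], colnames(dm)))]
      collected <- c(collected, as.integer(d[is.finite(d)]))
    }
    if (length(collected) == 0) {
      stop("no connected node pair found within the retry bound")
    }
    as.integer(lower_median(collected[seq_len(min(n_pairs, length(collected)))]))
  })
}

#' Degree index of a gene graph
#'
#' @param graph igraph gene graph.
#' @return list with `degree` (named integer vector, one entry per node) and
#'   `buckets` (list mapping degree, as character, to the genes of that
#'   degree).
#' @export
degree_index <- function(graph) {
  deg <- igraph::degree(graph)
  list(degree = deg, buckets = split(names(deg), deg))
}

#' Sample degree-matched control genes
#'
#' Draws one control gene per target, without replacement, matching each
#' target's degree exactly when possible and widening the allowed degree
#' band by +/-1 per step, up to `max_tolerance`, only when the current pool
#' is empty. Controls are never drawn from `targets` or `exclude`. Used to
#' build degree-controlled null gene sets for proximity testing and
#' degree-matched non-driver negatives for classifier training.
#'
#' @param graph igraph gene graph.
#' @param targets character vector of target genes (must be nodes).
#' @param exclude character vector of genes never to return.
#' @param max_tolerance maximum degree difference allowed (default 1,
#'   "within +/-1 degree if needed"). `Inf` widens the band until any
#'   eligible gene is found, which is required when the requested controls
#'   are a large fraction of the graph.
#' @param seed RNG seed.
#' @return character vector of matched genes, aligned with `targets`.
#' @export
sample_degree_matched <- function(graph, targets, exclude = character(0),
                                  max_tolerance = 1, seed = 1) {
  stopifnot(max_tolerance >= 0)
  targets <- as.character(targets)
  missing <- setdiff(targets, igraph::V(graph)$name)
  if (length(missing) > 0) {
    stop(sprintf("target gene(s) not in graph: %s", paste(missing, collapse = ", ")))
  }
  idx <- degree_index(graph)
  deg <- idx$degree
  forbidden <- unique(c(targets, as.character(exclude)))
  with_seed(seed, {
    chosen <- character(length(targets))
    taken <- character(0)
    max_deg <- max(deg)
    for (k in seq_along(targets)) {
      td <- deg[[targets[k]]]
      pool <- character(0)
      tol <- 0
      repeat {
        degs_ok <- as.character(seq(max(0, td - tol), min(max_deg, td + tol)))
        pool <- setdiff(unlist(idx$buckets[degs_ok], use.names = FALSE),
                        c(forbidden, taken))
        if (length(pool) > 0) break
        ## stop once the band cannot widen further or the tolerance is spent
        if (tol >= max_tolerance || (td - tol <= 0 && td + tol >= max_deg)) break
        tol <- tol + 1
      }
      if (length(pool) == 0) {
        stop(sprintf("no degree-matched control for gene '%s' (degree %d) at tolerance %d",
                     targets[k], td, max_tolerance))
      }
      chosen[k] <- pool[[sample.int(length(pool), 1L)]]
      taken <- c(taken, chosen[k])
    }
    chosen
  })
}
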