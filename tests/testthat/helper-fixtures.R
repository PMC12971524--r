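# Small in-code fixtures shared across test files.

# Build a gene graph from "A B [conf]" edge strings.
graph_from_edges <- function(edges, nodes = NULL) {
  parts <- strsplit(edges, " +")
  df <- data.frame(
    from = vapply(parts, `[[`, "", 1),
    to = vapply(parts, `[[`, "", 2),
    confidence = vapply(parts, function(p) {
      if (length(p) >= 3) as.integer(p[[3]]) else 500L
    }, 0L),
    stringsAsFactors = FALSE
  )
  gene_graph(df, nodes = nodes)
}

# Path graph A-B-C-...
path_graph <- function(labels) {
  graph_from_edges(paste(labels[-length(labels)], labels[-1]))
}

write_edge_tsv <- function(lines, path = tempfile(fileext = ".tsv"),
                           header = FALSE) {
  if (header) lines <- c("protein1\tprotein2\tcombined_score", lines)
  writeLines(lines, path)
  path
}

# Tiny planted benchmark used by several model tests.
small_sim <- function(seed = 42) {
  generate_synthetic(synth_config(
    n_genes = 600, p_bg = 0.004, n_sets = 3, set_size = 30,
    n_drivers = 40, p_signal = 0.15, p_noise = 0.01, seed = seed
  ))
}
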