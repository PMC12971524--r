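## Seeded synthetic-benchmark generator: random background graph with nine
## planted process modules and a planted driver set whose members have
## elevated edge probability to module members, plus differential tables
## with a planted consensus and a degree-preserving rewiring utility.
## Every pipeline stage can be exercised on these objects without any
## external download.

#' Configuration for the synthetic benchmark generator
#'
#' Defaults define the reference study conditions for the planted-signal
#' benchmark: a 3,000-gene background graph at edge probability 0.002, nine
#' planted modules of 60 genes, and 150 planted drivers attaching to module
#' members with probability 0.08 against a 0.01 non-driver baseline.
#'
#' @param n_genes number of genes.
#' @param p_bg background edge probability (Bernoulli over all pairs).
#' @param n_sets number of planted modules (9 mirrors the production
#'   collection: SR/WH/RG up+down plus three direction-agnostic sets).
#' @param set_size members per module.
#' @param n_drivers number of planted driver genes.
#' @param p_signal driver-to-module-member attachment probability.
#' @param p_noise non-driver-to-module-member attachment probability.
#' @param drivers_disjoint keep drivers disjoint from module members
#'   (default TRUE).
#' @param seed RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 3000, p_bg = 0.002, n_sets = 9,
                         set_size = 60, n_drivers = 150, p_signal = 0.08,
                         p_noise = 0.01, drivers_disjoint = TRUE, seed = 1) {
  stopifnot(p_noise >= 0, p_signal >= p_noise, p_signal <= 1,
            n_sets >= 1, set_size >= 1, n_drivers >= 1)
  needed <- n_sets * set_size + if (drivers_disjoint) n_drivers else 0
  if (needed > n_genes) stop("modules and drivers do not fit in n_genes")
  structure(
    list(n_genes = n_genes, p_bg = p_bg, n_sets = n_sets, set_size = set_size,
         n_drivers = n_drivers, p_signal = p_signal, p_noise = p_noise,
         drivers_disjoint = drivers_disjoint, seed = seed),
    class = "synth_config"
  )
}

## The nine production set names, recycled for other n_sets values.
.synth_set_meta <- function(n_sets) {
  base <- data.frame(
    name = c("SR-UP", "SR-DOWN", "WH-UP", "WH-DOWN", "RG-UP", "RG-DOWN",
             "SR-H", "WH-H", "RG-H"),
    process = c("SR", "SR", "WH", "WH", "RG", "RG", "SR", "WH", "RG"),
    direction = c("UP", "DOWN", "UP", "DOWN", "UP", "DOWN",
                  "AGNOSTIC", "AGNOSTIC", "AGNOSTIC"),
    stringsAsFactors = FALSE
  )
  if (n_sets <= 9) return(base[seq_len(n_sets), ])
  extra <- data.frame(name = paste0("SET-", seq(10, n_sets)),
                      process = "other", direction = "AGNOSTIC",
                      stringsAsFactors = FALSE)
  rbind(base, extra)
}

## Sample m distinct unordered pairs (as a 2-column index matrix) from the
## n*(n-1)/2 pairs over seq_len(n), by linear pair index.
.sample_pairs <- function(n, m) {
  total <- n * (n - 1) / 2
  idx <- sample(total, m)
  ## invert the row-major upper-triangle linearization
  i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * idx)) / 2) + 1
  base <- (i - 1) * n - i * (i - 1) / 2
  j <- idx - base + i
  ## guard against floating point edge cases
  bad <- j <= i | j > n
  if (any(bad)) {
    for (k in which(bad)) {
      ii <- 1
      rem <- idx[k]
      while (rem > n - ii) { rem <- rem - (n - ii); ii <- ii + 1 }
      i[k] <- ii; j[k] <- ii + rem
    }
  }
  cbind(as.integer(i), as.integer(j))
}

#' Generate a synthetic planted-module benchmark
#'
#' Draws a background Erdos-Renyi graph over `n_genes` genes, plants
#' `n_sets` disjoint modules, and adds extra edges from every driver to
#' every module member with probability `p_signal` and from every
#' non-driver with probability `p_noise`. With `p_signal > p_noise`,
#' drivers are closer to module members than degree-typical genes, so
#' proximity features separate drivers from non-drivers; with
#' `p_signal = p_noise` the construction is label-symmetric and carries no
#' signal. All edges get confidence 1000 minus a small jitter so
#' confidence filtering can be exercised. Output is deterministic under
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @param out_dir optional directory; when given, writes `edges.tsv`
#'   (edge-list TSV), `sets.gmt` and `drivers.txt` in the dialects the
#'   pipeline reads.
#' @return list with `graph` (igraph), `collection`
#'   ([gene_set_collection()]), `drivers` (character vector) and
#'   `nondrivers` (the remaining genes).
#' @export
generate_synthetic <- function(config = synth_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  with_seed(cfg$seed, {
    ## planted structure
    pool <- sample(genes)
    member_idx <- seq_len(cfg$n_sets * cfg$set_size)
    members_all <- pool[member_idx]
    sets <- split(members_all, rep(seq_len(cfg$n_sets), each = cfg$set_size))
    drivers <- if (cfg$drivers_disjoint) {
      pool[cfg$n_sets * cfg$set_size + seq_len(cfg$n_drivers)]
    } else {
      sample(genes, cfg$n_drivers)
    }
    ## background edges: Binomial count, then distinct sampled pairs
    m_bg <- stats::rbinom(1, cfg$n_genes * (cfg$n_genes - 1) / 2, cfg$p_bg)
    pr <- .sample_pairs(cfg$n_genes, m_bg)
    edges_from <- genes[pr[, 1]]
    edges_to <- genes[pr[, 2]]
    ## attachment edges gene -> module member
    others <- setdiff(genes, members_all)
    is_driver <- others %in% drivers
    p_attach <- ifelse(is_driver, cfg$p_signal, cfg$p_noise)
    n_other <- length(others)
    n_mem <- length(members_all)
    hit <- stats::runif(n_other * n_mem) < rep(p_attach, times = n_mem)
    oi <- rep(seq_len(n_other), times = n_mem)[hit]
    mi <- rep(seq_len(n_mem), each = n_other)[hit]
    edges_from <- c(edges_from, others[oi])
    edges_to <- c(edges_to, members_all[mi])
    conf <- 1000L - sample.int(100L, length(edges_from), replace = TRUE) + 1L
    graph <- gene_graph(data.frame(from = edges_from, to = edges_to,
                                   confidence = conf, stringsAsFactors = FALSE),
                        nodes = genes)
    if (igraph::vcount(graph) < 2 || igraph::ecount(graph) < 1) {
      stop("generated graph has fewer than 2 connected nodes")
    }
    meta <- .synth_set_meta(cfg$n_sets)
    collection <- gene_set_collection(lapply(seq_len(cfg$n_sets), function(i) {
      gene_set(meta$name[i], sets[[i]], process = meta$process[i],
               direction = meta$direction[i])
    }))
    out <- list(graph = graph, collection = collection, drivers = sort(drivers),
                nondrivers = sort(setdiff(genes, drivers)))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_network(graph, file.path(out_dir, "edges.tsv"))
      write_gmt(collection, file.path(out_dir, "sets.gmt"))
      writeLines(out$drivers, file.path(out_dir, "drivers.txt"))
    }
    out
  })
}

#' Generate differential tables with a planted consensus
#'
#' Emits `n_datasets` differential-expression tables (gene, log_fc, adj_p)
#' in which every planted gene is significantly upregulated (adjusted
#' p < 0.05, LFC >= 1) in exactly two tables, and every decoy gene in at
#' most one, so that the two-dataset consensus over the UP-filtered tables
#' recovers exactly the planted set.
#'
#' @param n_datasets number of tables (>= 2).
#' @param genes_per_table decoy genes per table (in addition to planted
#'   genes).
#' @param planted_consensus character vector of genes to plant.
#' @param seed RNG seed.
#' @return list of data.frames with columns `gene`, `log_fc`, `adj_p`.
#' @export
generate_differential_tables <- function(n_datasets = 5, genes_per_table = 200,
                                         planted_consensus = character(0),
                                         seed = 1) {
  stopifnot(n_datasets >= 2)
  planted <- unique(as.character(planted_consensus))
  with_seed(seed, {
    decoys <- sprintf("D%05d", seq_len(genes_per_table * n_datasets))
    ## each decoy is significant in at most one table
    decoy_sig_table <- sample(c(seq_len(n_datasets), NA), length(decoys),
                              replace = TRUE)
    planted_tables <- lapply(planted, function(g) sample(n_datasets, 2))
    lapply(seq_len(n_datasets), function(t) {
      dg <- sample(decoys, genes_per_table)
      dg_sig <- decoy_sig_table[match(dg, decoys)] == t
      dg_sig[is.na(dg_sig)] <- FALSE
      p_sig <- length(planted) > 0 &
        vapply(planted_tables, function(tt) t %in% tt, TRUE)
      gene <- c(planted, dg)
      sig <- c(p_sig, dg_sig)
      n <- length(gene)
      log_fc <- ifelse(sig, stats::runif(n, 1, 3), stats::runif(n, -0.5, 0.5))
      adj_p <- ifelse(sig, stats::runif(n, 0.001, 0.04), stats::runif(n, 0.2, 0.9))
      data.frame(gene = gene, log_fc = log_fc, adj_p = adj_p,
                 stringsAsFactors = FALSE)
    })
  })
}

#' Degree-preserving rewiring of a gene graph
#'
#' Randomizes the edge set by repeated double-edge swaps while preserving
#' every node's degree and the simple-graph constraint (swaps that would
#' create loops or parallel edges are rejected and retried). A null-model
#' utility for topology-dependent statistics. Edge confidences are not
#' meaningful after rewiring and are reset to 1000.
#'
#' @param graph igraph gene graph with >= 2 edges.
#' @param n_swaps number of attempted swaps.
#' @param seed RNG seed.
#' @return rewired igraph gene graph.
#' @export
degree_preserving_rewire <- function(graph, n_swaps, seed = 1) {
  if (igraph::ecount(graph) < 2) stop("graph must have at least 2 edges")
  if (n_swaps == 0) return(graph)
  with_seed(seed, {
    g2 <- igraph::rewire(graph, igraph::keeping_degseq(loops = FALSE,
                                                       niter = n_swaps))
    igraph::E(g2)$confidence <- 1000L
    g2
  })
}
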