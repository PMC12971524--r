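## Overlap enrichment (Fisher's exact test + Benjamini-Hochberg) and the
## ranked-table filters used by the cancer-association analyses (top-k%
## most-mutated / most-differential genes, hazard-ratio caps, dependency
## cutoffs).

#' Fisher overlap enrichment of two gene sets in a universe
#'
#' Builds the 2x2 overlap table of `a` and `b` within `universe` and tests
#' for enrichment. The one-sided (default) p-value is the hypergeometric
#' upper tail P\[X >= overlap\]; a two-sided option delegates to
#' [stats::fisher.test()]. The odds ratio is the raw cross-product ratio
#' `(overlap * neither) / (a_only * b_only)`, reported as `Inf` when a
#' denominator cell is zero (no continuity correction, so the printed
#' magnitudes are the plain table ratios). Members outside the universe are
#' intersected away with a logged count. The BH-adjusted `q` is left `NA`
#' until [adjust_bh()] is applied across a family of tests.
#'
#' @param a,b character vectors (or `gene_set`s) of gene identifiers.
#' @param universe character vector; the background gene universe, typically
#'   all genes present in the loaded network.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @param set_a,set_b names used in the output record.
#' @return one-row data.frame of class `enrichment_record` with columns
#'   `set_a`, `set_b`, `overlap`, `a_only`, `b_only`, `neither`,
#'   `odds_ratio`, `p`, `q`.
#' @export
fisher_overlap <- function(a, b, universe,
                           alternative = c("greater", "two.sided"),
                           set_a = "a", set_b = "b") {
  alternative <- match.arg(alternative)
  if (inherits(a, "gene_set")) { if (set_a == "a") set_a <- a$name; a <- a$members }
  if (inherits(b, "gene_set")) { if (set_b == "b") set_b <- b$name; b <- b$members }
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe must be non-empty")
  a <- unique(as.character(a)); b <- unique(as.character(b))
  n_out <- sum(!a %in% universe) + sum(!b %in% universe)
  if (n_out > 0) dp_log("%d set member(s) outside the universe were dropped", n_out)
  a <- intersect(a, universe); b <- intersect(b, universe)
  N <- length(universe)
  k <- length(intersect(a, b))
  a_only <- length(a) - k
  b_only <- length(b) - k
  neither <- N - k - a_only - b_only
  p <- if (alternative == "greater") {
    stats::phyper(k - 1, length(a), N - length(a), length(b), lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(k, a_only, b_only, neither), 2), alternative = "two.sided")$p.value
  }
  or <- if (a_only == 0 || b_only == 0) {
    if (k == 0 || neither == 0) NaN else Inf
  } else {
    (k * neither) / (a_only * b_only)
  }
  structure(
    data.frame(set_a = set_a, set_b = set_b, overlap = k, a_only = a_only,
               b_only = b_only, neither = neither, odds_ratio = or,
               p = p, q = NA_real_, stringsAsFactors = FALSE),
    class = c("enrichment_record", "data.frame")
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment: `p(i) * n / i` at each
#' ascending rank, with the cumulative minimum enforced from the largest
#' rank down, capped at 1. Input order is preserved.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted values, same order as the input.
#' @export
adjust_bh <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Construct a ranked gene table
#'
#' @param gene character vector of unique gene identifiers.
#' @param value numeric ranking values (e.g. mutation frequency, hazard
#'   ratio, dependency probability).
#' @param direction `"decreasing"` (default; larger values rank higher) or
#'   `"increasing"`.
#' @return data.frame of class `ranked_gene_table` with attribute
#'   `direction`.
#' @export
ranked_gene_table <- function(gene, value, direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("genes in a ranked table must be unique")
  out <- data.frame(gene = gene, value = as.numeric(value), stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  class(out) <- c("ranked_gene_table", "data.frame")
  out
}

#' Read a ranked gene table (TSV: gene, value)
#'
#' @param path TSV path with a header line.
#' @param direction declared sort direction; see [ranked_gene_table()].
#' @return a `ranked_gene_table`.
#' @export
read_ranked_table <- function(path, direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop(sprintf("ranked table '%s' needs at least 2 columns", path))
  ranked_gene_table(df[[1]], df[[2]], direction)
}

#' Extract the top fraction of a ranked gene table
#'
#' Returns the top `k = ceiling(fraction * nrow)` genes per the table's
#' declared sort direction, optionally capped at `max_n` (the
#' "top 1,000 if more were significant" rule for hazard-ratio tables). Ties
#' at the boundary value are broken by ascending gene identifier, so the
#' selection is deterministic.
#'
#' @param table a [ranked_gene_table()].
#' @param fraction real in (0, 1\]; e.g. 0.05 for the top 5% most
#'   frequently mutated genes, 0.10 for the top 10% most differentially
#'   expressed.
#' @param max_n optional cap on the number of genes returned.
#' @return character vector of selected genes.
#' @export
top_fraction <- function(table, fraction, max_n = NULL) {
  stopifnot(inherits(table, "ranked_gene_table"))
  if (nrow(table) == 0) stop("ranked table is empty")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  k <- ceiling(fraction * nrow(table))
  if (!is.null(max_n)) k <- min(k, max_n)
  v <- if (attr(table, "direction") == "decreasing") -table$value else table$value
  ord <- order(v, table$gene, method = "radix")
  table$gene[ord[seq_len(k)]]
}

#' Fraction of a ranked table at or above a cutoff
#'
#' Fraction of rows with `value >= cutoff`, optionally restricted to a gene
#' subset. With the conventional dependency-probability cutoff of 0.5 this
#' is the fraction of genes called essential.
#'
#' @param table a [ranked_gene_table()].
#' @param cutoff inclusive threshold.
#' @param genes optional character vector restricting the rows considered.
#' @return real in \[0, 1\].
#' @export
threshold_fraction <- function(table, cutoff = 0.5, genes = NULL) {
  stopifnot(inherits(table, "ranked_gene_table"))
  rows <- table
  if (!is.null(genes)) rows <- rows[rows$gene %in% genes, , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows in the (restricted) ranked table")
  mean(rows$value >= cutoff)
}
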