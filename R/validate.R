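## Fractional characterization of candidate gene lists against
## cancer-associated feature lists, and generic annotation enrichment for
## candidate sets.

#' Fraction of candidates carrying a feature
#'
#' @param candidates character vector of genes.
#' @param feature_set character vector (or `gene_set`) defining the feature
#'   (e.g. "among the top differentially expressed genes").
#' @return list with `k` (candidates in the feature set), `n` (candidate
#'   count) and `fraction` (= k/n).
#' @export
feature_fraction <- function(candidates, feature_set) {
  if (inherits(feature_set, "gene_set")) feature_set <- feature_set$members
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0) stop("candidate list is empty")
  k <- sum(candidates %in% feature_set)
  list(k = k, n = length(candidates), fraction = k / length(candidates))
}

#' Log-ratio comparison of two candidate lists against one feature
#'
#' Compares the fraction of genes carrying a feature between two candidate
#' lists (e.g. the high-scoring vs low-scoring candidate slices): the
#' statistic is `log2` of the ratio of continuity-corrected fractions
#' `(k + 0.5) / (n + 1)` for each side, which stays finite when a count is
#' zero. Raw fractions are reported alongside so the uncorrected ratio is
#' recoverable. Positive values mean list A is more concordant with the
#' feature than list B.
#'
#' @param candidates_a,candidates_b character vectors of genes.
#' @param feature_set character vector (or `gene_set`).
#' @param list_a,list_b,feature names used in the output.
#' @return one-row data.frame of class `fraction_comparison` with counts,
#'   raw fractions and `log2_ratio`.
#' @export
log_ratio <- function(candidates_a, candidates_b, feature_set,
                      list_a = "A", list_b = "B", feature = "feature") {
  fa <- feature_fraction(candidates_a, feature_set)
  fb <- feature_fraction(candidates_b, feature_set)
  corrected <- function(f) (f$k + 0.5) / (f$n + 1)
  structure(
    data.frame(list_a = list_a, list_b = list_b, feature = feature,
               k_a = fa$k, n_a = fa$n, k_b = fb$k, n_b = fb$n,
               frac_a = fa$fraction, frac_b = fb$fraction,
               log2_ratio = log2(corrected(fa) / corrected(fb)),
               stringsAsFactors = FALSE),
    class = c("fraction_comparison", "data.frame")
  )
}

#' Annotation enrichment of a candidate list
#'
#' Fisher overlap enrichment of the candidates against every set of an
#' annotation collection (any user-supplied GMT: pathway, ontology, or
#' custom), with Benjamini-Hochberg adjustment across the collection.
#' Results are sorted by adjusted q, then by descending odds ratio.
#'
#' @param candidates character vector of genes.
#' @param annotation a [gene_set_collection()].
#' @param universe background gene universe.
#' @return data.frame of `enrichment_record` rows with the `q` column
#'   filled.
#' @export
annotate_enrichment <- function(candidates, annotation, universe) {
  stopifnot(inherits(annotation, "gene_set_collection"))
  recs <- lapply(annotation, function(s) {
    fisher_overlap(candidates, s, universe, set_a = "candidates", set_b = s$name)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out$q <- adjust_bh(out$p)
  ord <- order(out$q, -out$odds_ratio, method = "radix")
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
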