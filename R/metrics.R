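## Threshold-free classifier metrics and the DeLong test for correlated
## ROC curves.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with half credit for ties: the
#' probability that a random positive is scored above a random negative,
#' counting ties as 1/2.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels 0/1 labels.
#' @return real in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration of the precision-recall curve: candidates are
#' swept in descending score order (tied scores entering together) and each
#' recall increment contributes `delta_recall * precision` at that
#' operating point. The baseline for a random classifier equals class
#' prevalence.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return real in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  ## group tied scores so the curve does not depend on within-tie order
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  n_pos <- sum(labels)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  d_recall <- diff(c(0, recall))
  sum(d_recall * precision)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUROCs of two score vectors computed on the same labeled
#' examples, using the fast midrank formulation of the DeLong
#' placement-value covariance. Returns the AUC difference and a two-sided
#' p-value from the normal reference.
#'
#' @param scores_a,scores_b numeric score vectors over the same examples.
#' @param labels shared 0/1 labels.
#' @return list with `delta_auc` (= auroc(a) - auroc(b)), `z`, and `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pos <- labels == 1; neg <- labels == 0
  m <- sum(pos); n <- sum(neg)
  placements <- function(s) {
    ## V10[i]: placement of positive i among negatives; V01[j]: of negative j
    r_all <- rank(s)
    r_pos <- rank(s[pos])
    r_neg <- rank(s[neg])
    v10 <- (r_all[pos] - r_pos) / n
    v01 <- 1 - (r_all[neg] - r_neg) / m
    list(v10 = v10, v01 = v01, auc = (sum(r_all[pos]) - m * (m + 1) / 2) / (m * n))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  delta <- pa$auc - pb$auc
  if (identical(scores_a, scores_b) || delta == 0 && isTRUE(all.equal(scores_a, scores_b))) {
    return(list(delta_auc = 0, z = 0, p = 1))
  }
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
               (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_delta <= 0) {
    if (abs(delta) < 1e-12) return(list(delta_auc = delta, z = 0, p = 1))
    stop("degenerate DeLong variance with a non-zero AUC difference")
  }
  z <- delta / sqrt(var_delta)
  list(delta_auc = delta, z = z, p = 2 * stats::pnorm(-abs(z)))
}
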