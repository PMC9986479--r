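# Conventional chance-adjusted external indices, computed from the
# contingency table of the two labellings. ARI is delegated to mclust; AMI,
# FMI and V-measure follow the standard definitions (the same ones behind
# scikit-learn's implementations, which the test suite uses as a frozen
# cross-check) because no installed R package provides them.

#' Adjusted Rand Index
#'
#' Pair-counting agreement between two labellings, adjusted for chance:
#' 1 for a perfect match (up to relabelling), about 0 for independent random
#' assignment. Delegates to [mclust::adjustedRandIndex()].
#'
#' @param true_labels,pred_labels equal-length integer label vectors.
#' @return a number in `[-1, 1]`.
#' @export
ari_score <- function(true_labels, pred_labels) {
  pair <- check_pair(true_labels, pred_labels)
  as.numeric(mclust::adjustedRandIndex(pair$truth, pair$pred))
}

contingency <- function(truth, pred) {
  table(factor(truth), factor(pred))
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Adjusted Mutual Information
#'
#' Mutual information between the two labellings, corrected by its
#' expectation under random permutations of the labels (hypergeometric
#' model) and normalised by the arithmetic mean of the two entropies:
#' `AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI])`. 1 for a perfect
#' match, about 0 for independent labellings.
#'
#' @inheritParams ari_score
#' @return a number, at most 1.
#' @export
ami_score <- function(true_labels, pred_labels) {
  pair <- check_pair(true_labels, pred_labels)
  n <- length(pair$truth)
  cont <- contingency(pair$truth, pair$pred)
  a <- rowSums(cont)
  b <- colSums(cont)
  # degenerate single-cluster / all-singleton agreement
  if ((length(a) == 1L && length(b) == 1L) ||
      (length(a) == n && length(b) == n)) return(1)
  mi <- mutual_information(cont, n)
  emi <- expected_mi(a, b, n)
  hu <- entropy_from_counts(a)
  hv <- entropy_from_counts(b)
  denom <- mean(c(hu, hv)) - emi
  if (abs(denom) < .Machine$double.eps) denom <- .Machine$double.eps
  (mi - emi) / denom
}

mutual_information <- function(cont, n) {
  nij <- as.numeric(cont)
  ai <- rep(rowSums(cont), times = ncol(cont))
  bj <- rep(colSums(cont), each = nrow(cont))
  pos <- nij > 0
  sum(nij[pos] / n * log(n * nij[pos] / (ai[pos] * bj[pos])))
}

# Expected mutual information under the permutation (hypergeometric) model.
expected_mi <- function(a, b, n) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      term <- (nij / n) * log(n * nij / (ai * bj))
      lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) + lgamma(n - bj + 1) -
        lgamma(n + 1) - lgamma(nij + 1) - lgamma(ai - nij + 1) -
        lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum(term * exp(lp))
    }
  }
  emi
}

#' Fowlkes-Mallows Index
#'
#' Geometric mean of pairwise precision and recall over point pairs placed
#' in the same cluster: 1 for a perfect match, 0 when no pair agrees.
#'
#' @inheritParams ari_score
#' @return a number in `[0, 1]`.
#' @export
fmi_score <- function(true_labels, pred_labels) {
  pair <- check_pair(true_labels, pred_labels)
  n <- length(pair$truth)
  cont <- contingency(pair$truth, pair$pred)
  tk <- sum(as.numeric(cont)^2) - n
  pk <- sum(rowSums(cont)^2) - n
  qk <- sum(colSums(cont)^2) - n
  if (tk == 0) return(0)
  sqrt(tk / pk) * sqrt(tk / qk)
}

#' V-measure
#'
#' Harmonic mean of homogeneity (each predicted cluster contains members of
#' a single true class) and completeness (all members of a true class land
#' in the same predicted cluster), both defined through conditional
#' entropies.
#'
#' @inheritParams ari_score
#' @return a number in `[0, 1]`.
#' @export
v_measure <- function(true_labels, pred_labels) {
  pair <- check_pair(true_labels, pred_labels)
  n <- length(pair$truth)
  cont <- contingency(pair$truth, pair$pred)
  hc <- entropy_from_counts(rowSums(cont))   # true classes
  hk <- entropy_from_counts(colSums(cont))   # predicted clusters
  mi <- mutual_information(cont, n)
  homogeneity <- if (hc == 0) 1 else mi / hc
  completeness <- if (hk == 0) 1 else mi / hk
  if (homogeneity + completeness == 0) return(0)
  2 * homogeneity * completeness / (homogeneity + completeness)
}
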