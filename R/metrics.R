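# External clustering validation: the Spike Cluster Score and Purity from
# their defining formulas, plus a suite wrapper adding the standard
# chance-adjusted indices.

check_pair <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels) || length(true_labels) < 1L)
    param_error("`true_labels` and `pred_labels` must be equal-length, non-empty")
  list(truth = as.integer(true_labels), pred = as.integer(pred_labels))
}

#' Spike Cluster Score
#'
#' An external validation metric designed for spike sorting, where splitting
#' one neuron's spikes into several clusters (overclustering) is recoverable
#' by later merging, but mixing neurons is not. For each unique true label
#' `T_i`, restrict the predictions to the points of `T_i`, find the
#' most frequent non-noise predicted label `P_j` there, and score
#'
#' \deqn{Score(T_i) = \frac{count(P(T_i) = P_j)}{count(P = P_j)}}
#'
#' i.e. the fraction of all of `P_j`'s occurrences that fall inside `T_i`.
#' The overall score is the unweighted mean over the unique true labels.
#'
#' Properties: a perfect clustering scores 1, as does assigning every sample
#' its own cluster (overclustering is never punished); annexing points of
#' *other* true clusters dilutes `P_j` and is punished; and because noise
#' predictions are never eligible as `P_j`, removing noise-predicted points
#' leaves the score unchanged.
#'
#' @param true_labels integer ground-truth labels.
#' @param pred_labels integer predicted labels.
#' @param noise_label predicted label to treat as noise (e.g. -1 for ISBM,
#'   0 for original SBM), or `NULL` when no noise convention applies.
#' @return a number in `[0, 1]`. The per-true-label breakdown is attached as
#'   `attr(, "breakdown")`.
#' @details Ties for the most frequent label are broken in favour of the
#'   candidate with the higher score (fewer occurrences elsewhere), then the
#'   smallest label value, so the metric is deterministic. A true cluster
#'   whose points are all predicted noise contributes a score of 0, with a
#'   warning.
#' @examples
#' spike_cluster_score(c(0, 0, 1, 1), c(5, 5, 7, 7))       # 1: relabelled perfect
#' spike_cluster_score(c(0, 0, 1), singleton_labeling(3))   # 1: overclustering
#' spike_cluster_score(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 0, 1, 1))  # 0.875
#' @export
spike_cluster_score <- function(true_labels, pred_labels, noise_label = NULL) {
  pair <- check_pair(true_labels, pred_labels)
  truth <- pair$truth
  pred <- pair$pred
  pvals <- sort(unique(pred))
  global <- tabulate(match(pred, pvals), nbins = length(pvals))
  tvals <- sort(unique(truth))
  scores <- numeric(length(tvals))
  for (i in seq_along(tvals)) {
    sub <- pred[truth == tvals[i]]
    if (!is.null(noise_label)) sub <- sub[sub != noise_label]
    if (length(sub) == 0L) {
      warning(sprintf("true label %d is entirely noise-predicted; its score is 0",
                      tvals[i]))
      scores[i] <- 0
      next
    }
    u <- sort(unique(sub))
    cnt <- tabulate(match(sub, u), nbins = length(u))
    cand <- u[cnt == max(cnt)]                       # ascending label order
    cand_scores <- max(cnt) / global[match(cand, pvals)]
    scores[i] <- cand_scores[which.max(cand_scores)] # max score, then smallest label
  }
  structure(mean(scores), breakdown = stats::setNames(scores, tvals))
}

#' Check the noise invariance of the Spike Cluster Score
#'
#' Verifies, for a concrete label pair, that removing all noise-predicted
#' positions leaves the Spike Cluster Score unchanged — the metric's design
#' guarantee that noise points cannot contaminate the evaluation.
#'
#' @inheritParams spike_cluster_score
#' @return `TRUE` iff the scores with and without the noise-predicted
#'   positions agree (trivially `TRUE` when no noise is present).
#' @details The guarantee presumes every true cluster keeps at least one
#'   non-noise prediction; a true cluster predicted entirely as noise scores
#'   0 before removal but vanishes from the mean after it, the one corner in
#'   which the check can return `FALSE` (the score itself warns there).
#' @export
scs_noise_invariance_check <- function(true_labels, pred_labels, noise_label = -1L) {
  pair <- check_pair(true_labels, pred_labels)
  full <- suppressWarnings(
    spike_cluster_score(pair$truth, pair$pred, noise_label = noise_label))
  keep <- pair$pred != noise_label
  if (all(keep) || !any(keep)) return(TRUE)
  reduced <- suppressWarnings(
    spike_cluster_score(pair$truth[keep], pair$pred[keep], noise_label = noise_label))
  isTRUE(all.equal(as.numeric(full), as.numeric(reduced), tolerance = 1e-12))
}

#' Purity
#'
#' The sum, over predicted clusters, of the largest overlap with any single
#' true label, divided by the number of samples. Perfect clustering scores 1
#' — but so does assigning each point its own cluster, so purity carries no
#' information about the number of clusters and should be read together with
#' chance-adjusted indices.
#'
#' @inheritParams spike_cluster_score
#' @return a number in `[0, 1]`.
#' @examples
#' purity(c(0, 0, 1, 1), c(0, 0, 0, 1))   # (2 + 1) / 4
#' @export
purity <- function(true_labels, pred_labels) {
  pair <- check_pair(true_labels, pred_labels)
  cont <- table(pair$pred, pair$truth)
  sum(apply(cont, 1L, max)) / length(pair$truth)
}

#' Compute the full metric suite for a label pair
#'
#' Spike Cluster Score and Purity natively; Adjusted Rand Index, Adjusted
#' Mutual Information, Fowlkes-Mallows Index and V-measure through standard
#' implementations. When `exclude_noise` is set, noise-predicted positions
#' are dropped before every metric *except* the Spike Cluster Score, which
#' is invariant to them by construction; the conventional metrics would
#' otherwise be contaminated by the noise points.
#'
#' @inheritParams spike_cluster_score
#' @param exclude_noise drop noise-predicted positions before the
#'   conventional metrics (default `FALSE`: evaluate on all labels,
#'   noise included).
#' @return data frame with columns `metric`, `raw` (native range) and
#'   `scaled` (raw times 100, for easier visual comparison); the per-true-label
#'   Spike Cluster Score breakdown is attached as `attr(, "scs_breakdown")`.
#' @examples
#' cloud <- generate_uo(seed = 1)
#' fit <- isbm_fit(cloud$points, PN = 30)
#' metric_suite(cloud$labels, fit$labels, noise_label = -1)
#' @export
metric_suite <- function(true_labels, pred_labels, noise_label = NULL,
                         exclude_noise = FALSE) {
  pair <- check_pair(true_labels, pred_labels)
  scs <- suppressWarnings(
    spike_cluster_score(pair$truth, pair$pred, noise_label = noise_label))
  truth <- pair$truth
  pred <- pair$pred
  if (exclude_noise && !is.null(noise_label)) {
    keep <- pred != noise_label
    if (!any(keep)) param_error("every prediction is noise; nothing to score")
    truth <- truth[keep]
    pred <- pred[keep]
  }
  raw <- c(
    ARI = ari_score(truth, pred),
    AMI = ami_score(truth, pred),
    Purity = purity(truth, pred),
    FMI = fmi_score(truth, pred),
    VM = v_measure(truth, pred),
    SCS = as.numeric(scs)
  )
  out <- data.frame(metric = names(raw), raw = unname(raw),
                    scaled = unname(raw) * 100)
  attr(out, "scs_breakdown") <- attr(scs, "breakdown")
  out
}
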