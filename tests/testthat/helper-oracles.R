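# Independent oracles used to check the package implementations. These are
# deliberately written as plain, slow enumerations straight from the
# definitions, sharing no code with the package internals.

# Spike Cluster Score, direct from its definition: for each unique true
# label take the most frequent non-noise predicted label in its subset
# (ties: higher resulting score, then smaller label) and divide its subset
# count by its global count; average unweighted over true labels.
scs_oracle <- function(truth, pred, noise = NULL) {
  per_label <- c()
  for (t in sort(unique(truth))) {
    sub <- pred[truth == t]
    if (!is.null(noise)) sub <- sub[sub != noise]
    if (length(sub) == 0) {
      per_label <- c(per_label, 0)
      next
    }
    best_count <- -1
    best_score <- -1
    for (j in sort(unique(sub))) {
      cnt <- sum(sub == j)
      score <- cnt / sum(pred == j)
      if (cnt > best_count || (cnt == best_count && score > best_score)) {
        best_count <- cnt
        best_score <- score
      }
    }
    per_label <- c(per_label, best_score)
  }
  mean(per_label)
}

# Purity, direct from its definition: largest single-true-label overlap of
# each predicted cluster, summed and divided by n.
purity_oracle <- function(truth, pred) {
  total <- 0
  for (j in unique(pred)) {
    overlaps <- sapply(unique(truth), function(t) sum(pred == j & truth == t))
    total <- total + max(overlaps)
  }
  total / length(truth)
}

# Nearest-centre assignment for a generated mixture.
nearest_centre <- function(points, centers) {
  d2 <- sapply(seq_along(centers), function(i)
    colSums((t(points) - centers[[i]])^2))
  max.col(-d2, ties.method = "first") - 1L
}

# Fraction of non-noise points whose predicted cluster maps, by majority,
# onto their reference label.
majority_accuracy <- function(pred, reference, noise_label) {
  keep <- pred != noise_label
  tab <- table(pred[keep], reference[keep])
  sum(apply(tab, 1L, max)) / sum(keep)
}

# Watershed-by-descent segmentation of a 1-D chunk-count profile, by
# explicit left/right walks instead of BFS: seeds are strict local maxima
# above the threshold, processed by descending count (ties: lower index),
# each claiming unlabelled cells outward while counts never increase.
watershed_1d <- function(counts, threshold) {
  m <- length(counts)
  is_seed <- logical(m)
  for (i in seq_len(m)) {
    left <- if (i > 1) counts[i - 1] else 0
    right <- if (i < m) counts[i + 1] else 0
    is_seed[i] <- counts[i] > threshold && counts[i] > left && counts[i] > right
  }
  seeds <- which(is_seed)
  seeds <- seeds[order(-counts[seeds], seeds)]
  labels <- integer(m)
  lab <- 0L
  for (s in seeds) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    labels[s] <- lab
    i <- s
    while (i > 1 && labels[i - 1] == 0L && counts[i - 1] > 0 &&
           counts[i - 1] <= counts[i]) {
      labels[i - 1] <- lab
      i <- i - 1
    }
    i <- s
    while (i < m && labels[i + 1] == 0L && counts[i + 1] > 0 &&
           counts[i + 1] <= counts[i]) {
      labels[i + 1] <- lab
      i <- i + 1
    }
  }
  labels
}

# 1-D point set whose chunkification at PN = length(counts) reproduces a
# given integer count profile (one cluster of points per cell midpoint).
points_from_counts <- function(counts) {
  mids <- seq_along(counts) - 0.5
  matrix(rep(mids, counts), ncol = 1)
}

# Same point partition up to label renumbering, with noise sets equal.
same_partition <- function(labels_a, noise_a, labels_b, noise_b) {
  if (!all((labels_a == noise_a) == (labels_b == noise_b))) return(FALSE)
  keep <- labels_a != noise_a
  if (!any(keep)) return(TRUE)
  a <- labels_a[keep]
  b <- labels_b[keep]
  all(tapply(b, a, function(v) length(unique(v))) == 1L) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1L)
}

# Random labelled pair in which every true label keeps at least one
# non-noise prediction (the regime the noise-invariance guarantee covers).
random_label_pair <- function(n, k_true = 3L, k_pred = 4L, noise_frac = 0.2) {
  truth <- sample.int(k_true, n, replace = TRUE) - 1L
  pred <- sample.int(k_pred, n, replace = TRUE) - 1L
  pred[runif(n) < noise_frac] <- -1L
  for (t in unique(truth)) {
    at <- which(truth == t)
    if (all(pred[at] == -1L)) pred[at[1L]] <- sample.int(k_pred, 1L) - 1L
  }
  list(truth = truth, pred = pred)
}
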