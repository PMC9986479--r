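# Improved Space Breakdown Method: sparse chunk graph + adaptive
# partitioning vector.
#
# Two changes relative to the dense-array original. First, only occupied
# chunks are stored, as nodes of a graph keyed by their integer coordinates;
# the node count V is bounded by both the sample count n and the number of
# cells, so memory is O(n) instead of O(PN^N). Second, the single
# partitioning number PN becomes the *maximum* partitions per dimension: each
# feature receives a partition count proportional to its variance (computed
# on [0,1]-normalised data so features are comparable), so low-information
# features are sliced coarsely. Labelling convention: clusters from 0,
# noise -1.

#' Variance-adaptive partitioning vector
#'
#' Computes per-feature population variances on `[0,1]` min-max-normalised
#' data, divides by the largest, and allots each feature
#' `ceil(PN * var_ratio)` partitions, clamped to `[2, PN]`. The
#' highest-variance feature gets exactly `PN` partitions; near-constant
#' features get the minimum of 2 (a single partition would carry no spatial
#' information).
#'
#' @param X numeric point cloud.
#' @param PN maximum partitions per dimension (at least 2).
#' @return object of class `partition_spec`: list with `PN` and the integer
#'   vector `PV` of length `N`.
#' @examples
#' X <- cbind(rnorm(200, sd = 2), rnorm(200, sd = 0.2))
#' compute_partition_vector(X, PN = 20)$PV
#' @export
compute_partition_vector <- function(X, PN) {
  X <- as_point_matrix(X)
  PN <- check_count(PN, "PN", min = 2L)
  rng <- apply(X, 2L, function(x) diff(range(x)))
  if (all(rng == 0))
    degenerate_error("all features are constant; no partitioning vector can be derived")
  vars <- vapply(seq_len(ncol(X)), function(j) {
    if (rng[j] == 0) return(0)
    pop_var((X[, j] - min(X[, j])) / rng[j])
  }, numeric(1))
  structure(list(PN = PN, PV = pv_from_variances(vars, PN)), class = "partition_spec")
}

# Partition counts from normalised-scale variances: ratio to the maximum,
# scaled by PN, rounded up, floored at 2.
pv_from_variances <- function(vars, PN) {
  if (max(vars) <= 0) degenerate_error("all feature variances are zero")
  as.integer(pmin(pmax(ceiling(PN * vars / max(vars)), 2L), PN))
}

#' Normalise each feature into its own partition range
#'
#' Maps feature `d` linearly onto `[0, PV_d]`; with a uniform vector
#' `PV = (PN, ..., PN)` this reduces exactly to [minmax_normalise()].
#'
#' @param X numeric point cloud.
#' @param PV integer vector of per-dimension partition counts.
#' @return numeric matrix, feature `d` in `[0, PV_d]`.
#' @export
normalise_with_pv <- function(X, PV) {
  X <- as_point_matrix(X)
  PV <- check_pv(PV, ncol(X))
  normalise_range(X, PV)
}

check_pv <- function(PV, N) {
  if (inherits(PV, "partition_spec")) PV <- PV$PV
  if (length(PV) != N || !is.numeric(PV) || any(PV != as.integer(PV)) || any(PV < 2))
    param_error(sprintf("`PV` must be an integer vector of length %d with entries >= 2", N))
  as.integer(PV)
}

chunk_key <- function(coords) {
  do.call(paste, c(lapply(seq_len(ncol(coords)), function(j) coords[, j]), sep = "_"))
}

#' Chunkify into a sparse chunk graph
#'
#' Floors (and clamps) the normalised coordinates of every point and creates
#' one graph node per *occupied* chunk, holding its point count, a label
#' initialised to 0 and a visited flag; empty chunks are never stored, so the
#' node count `V` never exceeds the sample count `n` (each point can at worst
#' found its own node with a count of 1) nor the total cell count
#' `prod(PV)`. Nodes are keyed by their coordinates joined with `"_"`; edges
#' are implicit between coordinate-adjacent nodes.
#'
#' @param Xn normalised point cloud with feature `d` in `[0, PV_d]`.
#' @param PV integer per-dimension partition counts.
#' @return object of class `chunk_graph`: coordinate matrix (0-based),
#'   `count`, `label`, `visited`, `keys`, `PV`, `n`.
#' @examples
#' Xn <- normalise_with_pv(matrix(rnorm(60), ncol = 2), PV = c(5, 5))
#' g <- chunkify_graph(Xn, PV = c(5, 5))
#' g$V <= 30
#' @export
chunkify_graph <- function(Xn, PV) {
  Xn <- as_point_matrix(Xn, "Xn")
  PV <- check_pv(PV, ncol(Xn))
  idx <- chunk_coords(Xn, PV)
  keys <- chunk_key(idx)
  first <- !duplicated(keys)
  coords <- idx[first, , drop = FALSE]
  ukeys <- keys[first]
  # canonical lexicographic node order
  o <- do.call(order, lapply(seq_len(ncol(coords)), function(j) coords[, j]))
  coords <- coords[o, , drop = FALSE]
  ukeys <- ukeys[o]
  count <- as.integer(tabulate(match(keys, ukeys), nbins = length(ukeys)))
  structure(list(coords = coords, count = count,
                 label = integer(length(ukeys)), visited = integer(length(ukeys)),
                 keys = ukeys, PV = PV, n = nrow(Xn), V = length(ukeys)),
            class = "chunk_graph")
}

#' @export
print.chunk_graph <- function(x, ...) {
  cat(sprintf("chunk graph: %d nodes over %s cells (PV = %s), %d points\n",
              x$V, format(prod(as.numeric(x$PV)), big.mark = ","),
              paste(x$PV, collapse = " "), x$n))
  invisible(x)
}

graph_lookup <- function(graph) {
  function(coord_matrix) match(chunk_key(coord_matrix), graph$keys)
}

#' Neighbouring chunk coordinates
#'
#' All chunks differing by at most one index in every dimension
#' (diagonal-inclusive adjacency), excluding the chunk itself and any
#' coordinate outside the grid; at most `3^N - 1` results. Cell `(0,0)` of a
#' 2-D grid therefore has exactly the neighbours `(0,1)`, `(1,0)` and
#' `(1,1)`.
#'
#' @param coord integer vector, one 0-based chunk coordinate.
#' @param PV integer per-dimension partition counts (grid extents).
#' @return integer matrix of neighbour coordinates, one per row.
#' @examples
#' chunk_neighbours(c(0, 0), PV = c(5, 5))
#' @export
chunk_neighbours <- function(coord, PV) {
  N <- length(coord)
  PV <- check_pv(PV, N)
  if (any(coord < 0) || any(coord >= PV))
    param_error("`coord` must lie inside the grid: 0 <= coord < PV")
  offs <- neighbour_offsets(N)
  cand <- sweep(offs, 2L, as.integer(coord), "+")
  ok <- rowSums(cand < 0L | cand >= rep(PV, each = nrow(cand))) == 0L
  cand[ok, , drop = FALSE]
}

#' Find centroid-candidate nodes in a chunk graph
#'
#' Identical candidacy rule and deterministic ordering as
#' [find_centroids_array()] — count above `threshold` and strictly greater
#' than every neighbour — except that only the `V` stored nodes are examined
#' and absent (empty) neighbours count as 0.
#'
#' @param graph a `chunk_graph`.
#' @param threshold minimum point count to seed a cluster.
#' @return integer matrix of candidate 0-based coordinates (rows ordered by
#'   descending count, ties by ascending coordinate), counts in
#'   `attr(, "count")`.
#' @export
find_centroids_graph <- function(graph, threshold = 5L) {
  stopifnot(inherits(graph, "chunk_graph"))
  threshold <- check_count(threshold, "threshold", min = 0L)
  keep <- local_maxima(graph$coords, graph$count, graph$PV,
                       graph_lookup(graph), threshold)
  order_candidates(graph$coords, graph$count, keep)
}

#' Expand centroid candidates over a chunk graph
#'
#' Same breadth-first descent semantics as [expand_array()] — non-increasing
#' counts from each density peak, pending candidates merged when reached —
#' restricted to the stored nodes; neighbours are resolved through the
#' implicit coordinate adjacency. Node labels and visited flags are filled
#' in place.
#'
#' @param graph a `chunk_graph`.
#' @param centroids candidate matrix from [find_centroids_graph()].
#' @return the `chunk_graph` with `label` (0 noise, clusters from 1,
#'   internal convention) and `visited` filled.
#' @export
expand_graph <- function(graph, centroids) {
  stopifnot(inherits(graph, "chunk_graph"))
  lookup <- graph_lookup(graph)
  cand_idx <- if (nrow(centroids) > 0L) lookup(centroids) else integer(0)
  if (anyNA(cand_idx)) param_error("centroid coordinates do not match graph nodes")
  adj <- build_adjacency(graph$coords, graph$PV, lookup)
  res <- expand_core(graph$count, adj, cand_idx)
  graph$label <- res$labels
  graph$visited <- res$visited
  graph$n_centroids <- length(cand_idx)
  graph$n_clusters <- res$n_clusters
  graph
}

#' @export
dechunkify.chunk_graph <- function(chunks, Xn) {
  Xn <- as_point_matrix(Xn, "Xn")
  idx <- chunk_coords(Xn, chunks$PV)
  node <- match(chunk_key(idx), chunks$keys)
  if (anyNA(node))
    contract_error("points fall outside the chunks the graph was built from")
  as.integer(chunks$label[node])
}

#' Cluster with the improved Space Breakdown Method
#'
#' Runs the graph-based pipeline: derive the variance-adaptive partitioning
#' vector (unless `pv` overrides it), normalise each feature into its own
#' partition range, chunkify into a sparse node graph, find centroid
#' candidates, expand by breadth-first descent, and dechunkify.
#' Clusters are labelled 0, 1, ... and noise -1 (the DBSCAN convention);
#' apart from this shift and the data structure, a uniform `pv` reproduces
#' the partition of [sbm_fit()] exactly.
#'
#' @param X numeric point cloud.
#' @param PN maximum partitions per dimension; see [suggest_pn()] for a
#'   starting point.
#' @param threshold minimum chunk count to seed a cluster (default 5).
#' @param pv optional explicit partitioning vector overriding the
#'   variance-adaptive one (e.g. `rep(PN, N)` for uniform partitioning).
#' @return an `sbm_clustering` object (see [sbm_fit()]) with
#'   `noise_label = -1` and the partitioning vector in `params$pv`.
#' @examples
#' cloud <- generate_uo(seed = 1)
#' fit <- isbm_fit(cloud$points, PN = 30, threshold = 5)
#' table(fit$labels)
#' @export
isbm_fit <- function(X, PN, threshold = 5L, pv = NULL) {
  X <- as_point_matrix(X)
  PN <- check_count(PN, "PN", min = 2L)
  threshold <- check_count(threshold, "threshold", min = 0L)
  PV <- if (is.null(pv)) compute_partition_vector(X, PN)$PV else check_pv(pv, ncol(X))
  Xn <- normalise_with_pv(X, PV)
  graph <- chunkify_graph(Xn, PV)
  cands <- find_centroids_graph(graph, threshold)
  graph <- expand_graph(graph, cands)
  internal <- dechunkify(graph, Xn)
  labels <- ifelse(internal == 0L, -1L, internal - 1L)
  new_clustering(as.integer(labels), noise_label = -1L, algorithm = "isbm",
                 chunk_stats = list(occupied = graph$V,
                                    total_cells = prod(as.numeric(PV)),
                                    centroids = nrow(cands)),
                 params = list(PN = PN, threshold = threshold, pv = PV))
}

#' Suggest a partitioning number
#'
#' A nearly optimal partitioning number can be estimated from how dispersed
#' the points are: `PN = round(n * max_var / 10)`, where `max_var` is the
#' largest per-feature population variance of the `[0,1]`-normalised data
#' (only the maximal variance matters because the adaptive partitioning
#' vector rescales the remaining features). The estimate is a starting point
#' for an exploratory search, not an optimum: on some datasets it is
#' suboptimal, so neighbouring values should be tried (see [tune_pn()]).
#'
#' @param X numeric point cloud.
#' @param cap upper clamp for the suggestion (default 50); the result is
#'   always at least 2.
#' @return a single integer partitioning number.
#' @examples
#' suggest_pn(generate_uo(seed = 1)$points)
#' @export
suggest_pn <- function(X, cap = 50L) {
  X <- as_point_matrix(X)
  cap <- check_count(cap, "cap", min = 2L)
  rng <- apply(X, 2L, function(x) diff(range(x)))
  if (all(rng == 0)) degenerate_error("all features are constant")
  vars <- vapply(seq_len(ncol(X)), function(j) {
    if (rng[j] == 0) return(0)
    pop_var((X[, j] - min(X[, j])) / rng[j])
  }, numeric(1))
  pn <- round(nrow(X) * max(vars) / 10)
  as.integer(min(max(pn, 2L), cap))
}

#' Exploratory search for the partitioning number
#'
#' Fits [isbm_fit()] for every value in `pn_grid` and returns the value
#' maximising an external metric against reference labels, mirroring the
#' recommended exploratory search around the [suggest_pn()] estimate. Ties
#' take the smallest partitioning number.
#'
#' @param X numeric point cloud.
#' @param truth reference integer labels (e.g. generator ground truth).
#' @param pn_grid integer vector of candidate partitioning numbers; default
#'   is a window around [suggest_pn()].
#' @param threshold minimum chunk count passed to [isbm_fit()].
#' @param metric `"ari"` (default) or `"scs"`.
#' @return list with the selected `PN`, the score `table` over the grid and
#'   the winning `fit`.
#' @export
tune_pn <- function(X, truth, pn_grid = NULL, threshold = 5L, metric = c("ari", "scs")) {
  metric <- match.arg(metric)
  X <- as_point_matrix(X)
  if (is.null(pn_grid)) {
    centre <- suggest_pn(X)
    pn_grid <- seq(max(2L, centre - 10L), centre + 10L, by = 2L)
  }
  pn_grid <- sort(unique(as.integer(pn_grid)))
  scores <- vapply(pn_grid, function(pn) {
    fit <- isbm_fit(X, PN = pn, threshold = threshold)
    if (metric == "ari") ari_score(truth, fit$labels)
    else spike_cluster_score(truth, fit$labels, noise_label = -1L)
  }, numeric(1))
  best <- pn_grid[which.max(scores)]
  list(PN = best,
       table = data.frame(PN = pn_grid, score = scores),
       fit = isbm_fit(X, PN = best, threshold = threshold))
}
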