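# Original Space Breakdown Method over a dense N-dimensional count array.
#
# Five sequential stages: min-max normalisation into [0, PN], chunkification
# into a dense PN^N count array, centroid-candidate search (strict local
# maxima above a minimum count threshold), breadth-first expansion along
# non-increasing counts, and dechunkification back to per-point labels.
# Original labelling convention: clusters 1, 2, ...; noise 0.

#' Min-max normalise a point cloud into `[0, PN]`
#'
#' Each feature is mapped linearly so that its minimum becomes 0 and its
#' maximum becomes `PN`: `x' = PN * (x - min) / (max - min)`. This is the
#' normalisation stage of the Space Breakdown Method; `PN` equal partitions
#' of each feature then correspond to unit-width intervals of the
#' normalised coordinates.
#'
#' @param X numeric matrix or data frame, `n` points by `N` features.
#' @param PN integer partitioning number, at least 2.
#' @return numeric matrix of the same shape with entries in `[0, PN]`.
#' @details A constant feature (max equal to min) has no defined min-max
#'   image and raises an error naming the offending column; drop or jitter
#'   such features before clustering.
#' @examples
#' minmax_normalise(matrix(c(0, 5, 10), ncol = 1), PN = 25)
#' @seealso [sbm_fit()], [normalise_with_pv()]
#' @export
minmax_normalise <- function(X, PN) {
  X <- as_point_matrix(X)
  PN <- check_count(PN, "PN", min = 2L)
  normalise_range(X, rep(PN, ncol(X)))
}

# Shared range mapper: feature d -> [0, scale_d].
normalise_range <- function(X, scale) {
  mins <- apply(X, 2L, min)
  maxs <- apply(X, 2L, max)
  flat <- which(maxs == mins)
  if (length(flat) > 0L)
    degenerate_error(sprintf(
      "feature column%s %s %s constant (max = min); min-max normalisation is undefined",
      if (length(flat) > 1L) "s" else "",
      paste(flat, collapse = ", "),
      if (length(flat) > 1L) "are" else "is"))
  Xn <- sweep(X, 2L, mins, "-")
  Xn <- sweep(Xn, 2L, maxs - mins, "/")
  sweep(Xn, 2L, scale, "*")
}

# 0-based chunk coordinates of normalised points: floor each coordinate,
# clamping a coordinate exactly equal to its extent into the last chunk.
chunk_coords <- function(Xn, extents) {
  n <- nrow(Xn)
  lo <- rowSums(Xn < 0) > 0L
  hi <- rowSums(Xn > rep(extents, each = n)) > 0L
  if (any(lo | hi))
    contract_error("normalised coordinates fall outside [0, extent]; normalise first")
  idx <- floor(Xn)
  cap <- rep(extents - 1L, each = n)
  idx[idx > cap] <- cap[idx > cap]
  storage.mode(idx) <- "integer"
  idx
}

#' Chunkify a normalised point cloud into a dense count array
#'
#' Maps every point to the chunk obtained by flooring its normalised
#' coordinates (a coordinate exactly equal to `PN` is clamped into the last
#' chunk) and stores the per-chunk point counts in a dense N-dimensional
#' array with `PN^N` cells.
#'
#' @param Xn normalised point cloud, entries in `[0, PN]`
#'   (see [minmax_normalise()]).
#' @param PN integer partitioning number used for the normalisation.
#' @param cell_budget refuse to allocate more than this many dense cells
#'   (default `getOption("sbmclust.cell_budget", 1e7)`). The dense array is
#'   exponential in the dimensionality; use [isbm_fit()] beyond the budget.
#' @return an object of class `chunk_array`: the count array plus bookkeeping
#'   (`PN`, dimensionality, point count). Total counts always sum to `n`.
#' @examples
#' Xn <- minmax_normalise(matrix(c(0, 1, 10, 2, 3, 30), ncol = 2), PN = 4)
#' ca <- chunkify_array(Xn, PN = 4)
#' sum(ca$counts)
#' @export
chunkify_array <- function(Xn, PN,
                           cell_budget = getOption("sbmclust.cell_budget", 1e7)) {
  Xn <- as_point_matrix(Xn, "Xn")
  PN <- check_count(PN, "PN", min = 2L)
  N <- ncol(Xn)
  total <- PN^N
  if (total > cell_budget)
    param_error(sprintf(
      "dense chunk array would need %s cells (PN^N = %d^%d) exceeding the cell budget %s; use isbm_fit() or raise `cell_budget`",
      format(total, big.mark = ","), PN, N, format(cell_budget, big.mark = ",")))
  idx <- chunk_coords(Xn, rep(PN, N))
  strides <- PN^(seq_len(N) - 1L)
  lin <- as.vector(idx %*% strides) + 1L
  counts <- array(tabulate(lin, nbins = as.integer(total)), dim = rep(PN, N))
  structure(list(counts = counts, labels = NULL, PN = PN, N = N, n = nrow(Xn)),
            class = "chunk_array")
}

# Occupied cells of a chunk array as a 0-based coordinate table.
occupied_cells <- function(chunks) {
  occ <- which(chunks$counts > 0L)
  coords <- arrayInd(occ, .dim = dim(chunks$counts)) - 1L
  list(lin = occ, coords = coords, count = as.integer(chunks$counts[occ]))
}

array_lookup <- function(chunks, occ) {
  strides <- chunks$PN^(seq_len(chunks$N) - 1L)
  function(coord_matrix) {
    lin <- as.vector(coord_matrix %*% strides) + 1L
    match(lin, occ$lin)
  }
}

#' Find centroid-candidate chunks in a dense count array
#'
#' A chunk is a centroid candidate when its count exceeds `threshold` and is
#' strictly greater than the count of every neighbouring chunk, neighbours
#' being all chunks differing by at most one index in every dimension
#' (diagonal-inclusive, so cell `(0,0)` neighbours `(0,1)`, `(1,0)` and
#' `(1,1)`). Candidates are returned sorted by descending count with ties
#' broken by ascending lexicographic coordinate; this fixed order makes the
#' subsequent expansion fully deterministic.
#'
#' @param chunks a `chunk_array` from [chunkify_array()].
#' @param threshold minimum point count a chunk must exceed to seed a
#'   cluster; a guard against crowning small conglomerations of noise points.
#' @return integer matrix of 0-based chunk coordinates, one candidate per
#'   row, with the candidate counts in `attr(, "count")`. May have 0 rows.
#' @export
find_centroids_array <- function(chunks, threshold = 5L) {
  stopifnot(inherits(chunks, "chunk_array"))
  threshold <- check_count(threshold, "threshold", min = 0L)
  occ <- occupied_cells(chunks)
  keep <- local_maxima(occ$coords, occ$count, rep(chunks$PN, chunks$N),
                       array_lookup(chunks, occ), threshold)
  order_candidates(occ$coords, occ$count, keep)
}

# Strict local-maximum test shared by both structures. `lookup` maps
# candidate coordinates to node indices (NA when the chunk is empty or
# absent; such neighbours count as 0).
local_maxima <- function(coords, count, upper, lookup, threshold) {
  V <- nrow(coords)
  is_max <- count > threshold
  offs <- neighbour_offsets(ncol(coords))
  for (o in seq_len(nrow(offs))) {
    if (!any(is_max)) break
    shifted <- sweep(coords, 2L, offs[o, ], "+")
    ok <- rowSums(shifted < 0L | shifted >= rep(upper, each = V)) == 0L
    nb_count <- integer(V)
    if (any(ok)) {
      idx <- lookup(shifted[ok, , drop = FALSE])
      got <- !is.na(idx)
      vals <- integer(sum(ok))
      vals[got] <- count[idx[got]]
      nb_count[ok] <- vals
    }
    is_max <- is_max & (count > nb_count)
  }
  is_max
}

order_candidates <- function(coords, count, keep) {
  sel <- which(keep)
  if (length(sel) == 0L) {
    out <- matrix(integer(0), nrow = 0L, ncol = ncol(coords))
    attr(out, "count") <- integer(0)
    return(out)
  }
  csel <- coords[sel, , drop = FALSE]
  o <- centroid_order(count[sel], csel)
  out <- csel[o, , drop = FALSE]
  attr(out, "count") <- count[sel][o]
  out
}

#' Expand centroid candidates over a dense chunk array
#'
#' Processes candidates in their sorted order and grows each cluster by
#' breadth-first search: a neighbouring chunk joins the frontier when it is
#' still unlabelled, occupied, and its count does not exceed the count of the
#' chunk it is reached from (clusters only flow "downhill" from density
#' peaks). A pending candidate reached this way is merged into the growing
#' cluster instead of seeding its own. Chunks never reached keep the noise
#' label 0.
#'
#' @param chunks a `chunk_array`.
#' @param centroids candidate coordinate matrix from [find_centroids_array()].
#' @return the `chunk_array` with a `labels` array filled in (0 noise,
#'   clusters numbered from 1 in processing order).
#' @export
expand_array <- function(chunks, centroids) {
  stopifnot(inherits(chunks, "chunk_array"))
  occ <- occupied_cells(chunks)
  lookup <- array_lookup(chunks, occ)
  cand_idx <- if (nrow(centroids) > 0L) lookup(centroids) else integer(0)
  if (anyNA(cand_idx)) param_error("centroid coordinates do not match occupied chunks")
  adj <- build_adjacency(occ$coords, rep(chunks$PN, chunks$N), lookup)
  res <- expand_core(occ$count, adj, cand_idx)
  labels <- array(0L, dim = dim(chunks$counts))
  labels[occ$lin] <- res$labels
  chunks$labels <- labels
  chunks$n_centroids <- length(cand_idx)
  chunks$n_clusters <- res$n_clusters
  chunks
}

#' Map chunk labels back to per-point labels
#'
#' The inverse of chunkification: each point receives the label of the chunk
#' its floored (and clamped) normalised coordinates fall into. Points whose
#' chunk was never claimed by any expansion keep the noise label.
#'
#' @param chunks a labelled `chunk_array` (from [expand_array()]) or
#'   `chunk_graph` (from [expand_graph()]).
#' @param Xn the normalised point cloud the chunks were built from.
#' @return integer label vector of length `n` (internal convention: noise 0,
#'   clusters from 1; [sbm_fit()] and [isbm_fit()] translate to their
#'   published conventions).
#' @export
dechunkify <- function(chunks, Xn) UseMethod("dechunkify")

#' @export
dechunkify.chunk_array <- function(chunks, Xn) {
  if (is.null(chunks$labels)) param_error("chunk labels not filled; run expand_array() first")
  Xn <- as_point_matrix(Xn, "Xn")
  idx <- chunk_coords(Xn, rep(chunks$PN, chunks$N))
  strides <- chunks$PN^(seq_len(chunks$N) - 1L)
  as.integer(chunks$labels[as.vector(idx %*% strides) + 1L])
}

#' Cluster with the original Space Breakdown Method
#'
#' Runs the five-stage pipeline — min-max normalisation into `[0, PN]`,
#' chunkification into a dense `PN^N` count array, centroid-candidate
#' search, breadth-first expansion, dechunkification — and returns per-point
#' labels in the original convention: clusters numbered from 1, noise 0.
#' The method is fully deterministic: identical input yields identical
#' labels.
#'
#' @param X numeric point cloud, `n` points by `N` features.
#' @param PN partitioning number: each feature is split into `PN` equal
#'   chunks. Coarse values merge close clusters; fine values fragment them.
#'   [suggest_pn()] gives a starting point for an exploratory search.
#' @param threshold minimum chunk count to seed a cluster (default 5); noise
#'   conglomerations below it can never crown a cluster.
#' @param cell_budget see [chunkify_array()].
#' @return an object of class `sbm_clustering` with elements `labels`,
#'   `noise_label` (0), `n_clusters`, `n_noise`, `chunk_stats` (occupied
#'   chunks, total dense cells, centroid candidates) and `params`.
#' @examples
#' cloud <- generate_mixture(list(
#'   list(center = c(0, 0), size = 100, sd = 0.5),
#'   list(center = c(10, 10), size = 100, sd = 0.5)), seed = 1)
#' fit <- sbm_fit(cloud$points, PN = 10, threshold = 1)
#' fit$n_clusters
#' @seealso [isbm_fit()] for the graph-based variant with adaptive
#'   per-dimension partitioning.
#' @export
sbm_fit <- function(X, PN, threshold = 5L,
                    cell_budget = getOption("sbmclust.cell_budget", 1e7)) {
  X <- as_point_matrix(X)
  PN <- check_count(PN, "PN", min = 2L)
  threshold <- check_count(threshold, "threshold", min = 0L)
  Xn <- minmax_normalise(X, PN)
  chunks <- chunkify_array(Xn, PN, cell_budget = cell_budget)
  cands <- find_centroids_array(chunks, threshold)
  chunks <- expand_array(chunks, cands)
  labels <- dechunkify(chunks, Xn)
  new_clustering(labels, noise_label = 0L, algorithm = "sbm",
                 chunk_stats = list(occupied = sum(chunks$counts > 0L),
                                    total_cells = PN^chunks$N,
                                    centroids = nrow(cands)),
                 params = list(PN = PN, threshold = threshold))
}

new_clustering <- function(labels, noise_label, algorithm, chunk_stats, params) {
  structure(list(
    labels = labels,
    noise_label = noise_label,
    n_clusters = length(setdiff(unique(labels), noise_label)),
    n_noise = sum(labels == noise_label),
    chunk_stats = chunk_stats,
    params = params,
    algorithm = algorithm
  ), class = "sbm_clustering")
}

#' @export
print.sbm_clustering <- function(x, ...) {
  cat(sprintf("%s clustering: %d points, %d clusters, %d noise (label %d)\n",
              toupper(x$algorithm), length(x$labels), x$n_clusters,
              x$n_noise, x$noise_label))
  cs <- x$chunk_stats
  cat(sprintf("  chunks: %s occupied of %s cells, %d centroid candidates\n",
              format(cs$occupied, big.mark = ","),
              format(cs$total_cells, big.mark = ","), cs$centroids))
  if (!is.null(x$params$pv))
    cat("  partitioning vector:", paste(x$params$pv, collapse = " "), "\n")
  invisible(x)
}
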