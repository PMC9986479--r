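# Shared cluster-expansion core.
#
# Both the dense-array and the sparse-graph pipelines expand seed chunks with
# the same semantics; they differ only in how chunks are stored and how
# neighbours are resolved. The caller supplies a per-node neighbour index
# matrix and the seed candidates already in processing order; this core runs
# the breadth-first descent and returns internal labels (0 = never reached,
# clusters numbered 1.. in seed processing order).
#
# Expansion rules, for a frontier chunk `cur` with neighbour `nb`:
#   * `nb` joins the cluster iff it is unlabelled, occupied, and
#     count[nb] <= count[cur] (non-increasing descent from the density peak);
#   * if `nb` is itself a pending seed candidate and the descent condition
#     holds, its would-be cluster is merged into the current one (the
#     candidate is dropped from the pending list). Under strict local-maximum
#     candidacy a candidate exceeds every neighbour's count, so this merge is
#     reachable only in principle; it is kept for fidelity to the published
#     procedure, which allows candidates to "be merged later on".

expand_core <- function(count, adjacency, candidate_idx) {
  V <- length(count)
  labels <- integer(V)
  visited <- integer(V)
  pending <- logical(V)
  pending[candidate_idx] <- TRUE

  next_label <- 0L
  queue <- integer(V)

  for (seed in candidate_idx) {
    if (!pending[seed]) next        # merged into an earlier cluster
    pending[seed] <- FALSE
    if (labels[seed] != 0L) next
    next_label <- next_label + 1L
    labels[seed] <- next_label

    queue[1L] <- seed
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      cur <- queue[head]
      head <- head + 1L
      visited[cur] <- 1L
      nbs <- adjacency[cur, ]
      nbs <- nbs[!is.na(nbs)]
      for (nb in nbs) {
        if (labels[nb] == 0L && count[nb] <= count[cur]) {
          labels[nb] <- next_label
          if (pending[nb]) pending[nb] <- FALSE
          tail <- tail + 1L
          if (tail > length(queue)) queue <- c(queue, integer(V))
          queue[tail] <- nb
        }
      }
    }
  }
  list(labels = labels, visited = visited, n_clusters = next_label)
}

# Neighbour index matrix for a set of occupied chunks identified by their
# 0-based integer coordinates. `lookup(coord_matrix)` must map candidate
# coordinates to node indices (NA when the chunk is absent or empty); the
# offset enumeration order is fixed so both pipelines traverse identically.
build_adjacency <- function(coords, upper, lookup) {
  V <- nrow(coords)
  N <- ncol(coords)
  offs <- neighbour_offsets(N)
  adj <- matrix(NA_integer_, nrow = V, ncol = nrow(offs))
  for (o in seq_len(nrow(offs))) {
    shifted <- sweep(coords, 2L, offs[o, ], "+")
    ok <- rowSums(shifted < 0L | shifted >= rep(upper, each = V)) == 0L
    if (any(ok)) {
      idx <- rep(NA_integer_, V)
      idx[ok] <- lookup(shifted[ok, , drop = FALSE])
      adj[, o] <- idx
    }
  }
  adj
}
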