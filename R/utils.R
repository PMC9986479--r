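# Internal helpers: input validation, classed errors, local RNG scope.

stop_sbm <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "sbmclust_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

param_error <- function(msg) stop_sbm(msg, "sbmclust_param_error")

degenerate_error <- function(msg) stop_sbm(msg, "sbmclust_degenerate_error")

contract_error <- function(msg) stop_sbm(msg, "sbmclust_contract_error")

# Coerce a point cloud to a numeric matrix (n x N) and validate it.
as_point_matrix <- function(X, arg = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, ncol = 1L)
  if (!is.matrix(X) || !is.numeric(X))
    param_error(sprintf("`%s` must be a numeric matrix or data frame", arg))
  if (nrow(X) < 1L || ncol(X) < 1L)
    param_error(sprintf("`%s` must have at least one row and one column", arg))
  if (!all(is.finite(X)))
    param_error(sprintf("`%s` contains non-finite entries", arg))
  X
}

check_count <- function(x, arg, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != as.integer(x) || x < min)
    param_error(sprintf("`%s` must be a single integer >= %d", arg, min))
  as.integer(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state (one seeded stream per call, no hidden global state).
with_local_seed <- function(seed, expr) {
  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed))
    param_error("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Population variance (divide by n); fixed for reproducibility.
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

# All 3^N - 1 coordinate offsets to diagonal-inclusive neighbours, in a
# fixed enumeration order shared by the array and graph pipelines so that
# BFS traversal (and hence contested-chunk assignment) is identical.
neighbour_offsets <- function(N) {
  grid <- as.matrix(do.call(expand.grid, rep(list(c(-1L, 0L, 1L)), N)))
  dimnames(grid) <- NULL
  grid[rowSums(grid != 0L) > 0L, , drop = FALSE]
}

# Deterministic seed-candidate ordering: descending count, ties broken by
# ascending lexicographic chunk coordinate.
centroid_order <- function(count, coords) {
  do.call(order, c(list(-count), lapply(seq_len(ncol(coords)), function(j) coords[, j])))
}
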