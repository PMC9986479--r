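# Synthetic point clouds with the structure the clustering method targets:
# imbalanced, overlapping, isotropic Gaussian clusters.

#' Cluster specification list for the Unbalance-Overlapping dataset
#'
#' The printed composition of the two-dimensional "Unbalance-Overlapping"
#' (UO) benchmark: 4,300 points in six Gaussian clusters of sizes 500, 50,
#' 1,000, 1,250, 250 and 1,250 centred at `[-2,0]`, `[-2,3]`, `[3,-2]`,
#' `[5,6]`, `[4,-1]` and `[1,-2]`. The per-cluster standard deviation is not
#' part of the printed composition; the default of 1 unit (isotropic) makes
#' the 3-unit spacing between the closest centres produce clusters that are
#' visibly distinct yet overlapping.
#'
#' @param sd isotropic per-dimension standard deviation (default 1).
#' @return list of cluster specs (`center`, `size`, `sd`) accepted by
#'   [generate_mixture()].
#' @export
uo_cluster_specs <- function(sd = 1.0) {
  if (length(sd) != 1L || !is.numeric(sd) || !is.finite(sd) || sd <= 0)
    param_error("`sd` must be a single positive number")
  centers <- list(c(-2, 0), c(-2, 3), c(3, -2), c(5, 6), c(4, -1), c(1, -2))
  sizes <- c(500L, 50L, 1000L, 1250L, 250L, 1250L)
  mapply(function(ct, sz) list(center = ct, size = sz, sd = c(sd, sd)),
         centers, sizes, SIMPLIFY = FALSE)
}

validate_specs <- function(specs) {
  if (!is.list(specs) || length(specs) < 1L)
    param_error("`specs` must be a non-empty list of cluster specs")
  dims <- integer(length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (!is.list(s) || is.null(s$center) || is.null(s$size) || is.null(s$sd))
      param_error(sprintf("spec %d must have fields `center`, `size`, `sd`", i))
    if (!is.numeric(s$center) || !all(is.finite(s$center)))
      param_error(sprintf("spec %d: `center` must be finite numeric", i))
    if (length(s$size) != 1L || s$size < 1 || s$size != as.integer(s$size))
      param_error(sprintf("spec %d: `size` must be a positive integer", i))
    sd <- s$sd
    if (length(sd) == 1L) sd <- rep(sd, length(s$center))
    if (length(sd) != length(s$center) || !all(is.finite(sd)) || any(sd <= 0))
      param_error(sprintf("spec %d: `sd` must be positive, length 1 or length(center)", i))
    specs[[i]]$sd <- sd
    specs[[i]]$size <- as.integer(s$size)
    dims[i] <- length(s$center)
  }
  if (length(unique(dims)) != 1L)
    param_error("all cluster specs must share the same dimensionality")
  specs
}

#' Generate an isotropic/diagonal Gaussian mixture with exact cluster sizes
#'
#' Samples cluster `c` as `size_c` draws from `N(center_c, diag(sd_c^2))`,
#' concatenated in spec order; ground-truth labels are 0-based and
#' block-ordered (shuffle with a seeded permutation if row order matters).
#' Per-cluster counts match the specs exactly — there is no rejection or
#' truncation — and output is bit-identical for a fixed seed.
#'
#' @param specs list of cluster specs: each a list with `center` (numeric
#'   vector), `size` (positive integer) and `sd` (positive; scalar or
#'   per-dimension).
#' @param seed integer seed for the one RNG stream used by the call; the
#'   caller's RNG state is left untouched.
#' @return object of class `labeled_cloud`: `points` (matrix `n x N`),
#'   `labels` (0-based integer ground truth), `k`, `sizes`.
#' @examples
#' cloud <- generate_mixture(list(
#'   list(center = c(0, 0), size = 3, sd = 1),
#'   list(center = c(5, 5), size = 5, sd = 1)), seed = 42)
#' table(cloud$labels)
#' @export
generate_mixture <- function(specs, seed) {
  specs <- validate_specs(specs)
  N <- length(specs[[1L]]$center)
  with_local_seed(seed, {
    blocks <- lapply(specs, function(s) {
      pts <- matrix(rnorm(s$size * N), nrow = s$size, ncol = N)
      pts <- sweep(pts, 2L, s$sd, "*")
      sweep(pts, 2L, s$center, "+")
    })
    points <- do.call(rbind, blocks)
    sizes <- vapply(specs, function(s) s$size, integer(1))
    labels <- rep(seq_along(specs) - 1L, times = sizes)
    structure(list(points = points, labels = labels,
                   k = length(specs), sizes = sizes),
              class = "labeled_cloud")
  })
}

#' Generate the Unbalance-Overlapping benchmark dataset
#'
#' Exactly 4,300 two-dimensional points in six isotropic Gaussian clusters
#' of sizes 500, 50, 1,000, 1,250, 250 and 1,250 at the printed centres (see
#' [uo_cluster_specs()]). The mix of a 50-point cluster adjacent to a
#' 500-point one, and several centres 3-4 units apart at unit spread, gives
#' the imbalance-plus-overlap structure that defeats centroid- and
#' density-based algorithms alike.
#'
#' @param seed integer seed; output is deterministic given the seed.
#' @param sd isotropic cluster standard deviation (default 1).
#' @return a `labeled_cloud` with `n = 4300` and `k = 6`.
#' @examples
#' cloud <- generate_uo(seed = 0)
#' nrow(cloud$points); table(cloud$labels)
#' @export
generate_uo <- function(seed, sd = 1.0) {
  generate_mixture(uo_cluster_specs(sd), seed)
}

#' Generate a scaled Unbalance-Overlapping dataset
#'
#' The same six clusters with every size multiplied by `n / 4300` (largest
#' cluster absorbs rounding), for runtime-scaling experiments on growing
#' sample counts.
#'
#' @param n total number of points.
#' @param seed integer seed.
#' @param sd isotropic cluster standard deviation.
#' @return a `labeled_cloud` with `n` points.
#' @export
generate_uo_scaled <- function(n, seed, sd = 1.0) {
  n <- check_count(n, "n", min = 6L)
  specs <- uo_cluster_specs(sd)
  base <- vapply(specs, function(s) s$size, integer(1))
  sizes <- pmax(1L, as.integer(round(base * n / sum(base))))
  sizes[which.max(sizes)] <- sizes[which.max(sizes)] + (n - sum(sizes))
  for (i in seq_along(specs)) specs[[i]]$size <- sizes[i]
  generate_mixture(specs, seed)
}

#' Singleton labelling
#'
#' Labels `n` points each as its own cluster: `0, 1, ..., n-1`. A useful
#' fixture for metric properties — both Purity and the Spike Cluster Score
#' rate this degenerate overclustering as perfect.
#'
#' @param n positive integer.
#' @return integer vector `0:(n-1)`.
#' @export
singleton_labeling <- function(n) {
  n <- check_count(n, "n", min = 1L)
  seq_len(n) - 1L
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("labeled cloud: %d points, %d dims, %d clusters (sizes %s)\n",
              nrow(x$points), ncol(x$points), x$k, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Write a labelled point cloud as CSV
#'
#' One row per point: feature columns `V1..VN` then a `label` column, with a
#' header row.
#'
#' @param cloud a `labeled_cloud` (or a list with `points` and `labels`).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_labeled_cloud <- function(cloud, file) {
  df <- as.data.frame(cloud$points)
  names(df) <- paste0("V", seq_len(ncol(df)))
  df$label <- cloud$labels
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a point cloud from delimited text
#'
#' @param file path to a CSV/TSV of numeric columns, optionally with a label
#'   column.
#' @param delimiter field delimiter (default `","`).
#' @param header whether the file has a header row (default `TRUE`).
#' @param label_column name or index of a ground-truth label column to split
#'   off (default: a column named `label` if present, else none).
#' @return list with `points` (numeric matrix) and `labels` (integer vector
#'   or `NULL`).
#' @export
read_point_cloud <- function(file, delimiter = ",", header = TRUE,
                             label_column = NULL) {
  df <- utils::read.table(file, sep = delimiter, header = header)
  if (is.null(label_column) && "label" %in% names(df)) label_column <- "label"
  labels <- NULL
  if (!is.null(label_column)) {
    labels <- as.integer(df[[label_column]])
    df[[if (is.numeric(label_column)) names(df)[label_column] else label_column]] <- NULL
  }
  list(points = as_point_matrix(df, "file contents"), labels = labels)
}

#' Write a label vector as a single-column CSV
#'
#' @param labels integer label vector, aligned to the input row order.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_labels <- function(labels, file) {
  write.csv(data.frame(label = as.integer(labels)), file, row.names = FALSE)
  invisible(file)
}
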