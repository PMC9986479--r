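# Benchmark harness: run SBM/ISBM and a roster of classical algorithms on
# generated or user-supplied datasets, score each with the metric suite, and
# report chunk/node statistics and runtime scaling.

#' Deterministic PCA projection
#'
#' Principal-component scores with a fixed sign convention (the largest-
#' magnitude loading of each component is made positive), so repeated runs
#' and different BLAS builds agree on the projection used for
#' dimensionality reduction.
#'
#' @param X numeric matrix.
#' @param d number of components to keep.
#' @return score matrix, `n` by `d`.
#' @export
pca_reduce <- function(X, d) {
  X <- as_point_matrix(X)
  d <- check_count(d, "d", min = 1L)
  if (d > ncol(X)) param_error("`d` exceeds the data dimensionality")
  if (d == ncol(X)) return(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sweep(scale(X, center = pc$center, scale = FALSE) %*% rot, 2L, flip, "*")
}

#' Chunk and node counts across dimensionalities
#'
#' For each requested dimensionality `d` (the data is PCA-reduced when
#' `d < N`), reports the dense cell count `PN^d` the original array
#' structure would allocate, the number of occupied nodes the sparse graph
#' stores under uniform partitioning, and the node count under the
#' variance-adaptive partitioning vector. The dense column is analytic;
#' the node columns require one chunkification each and are always bounded
#' by the sample count.
#'
#' @param X numeric point cloud.
#' @param PN partitioning number.
#' @param dims integer vector of dimensionalities to evaluate (each at most
#'   `ncol(X)`).
#' @return data frame with columns `dims`, `dense_cells`, `graph_nodes`
#'   (uniform partitioning) and `adaptive_nodes`.
#' @examples
#' cloud <- generate_uo(seed = 1)
#' chunk_statistics(cloud$points, PN = 25, dims = 2)
#' @export
chunk_statistics <- function(X, PN, dims) {
  X <- as_point_matrix(X)
  PN <- check_count(PN, "PN", min = 2L)
  dims <- vapply(dims, check_count, integer(1), arg = "dims", min = 1L)
  if (any(dims > ncol(X))) param_error("`dims` entries must not exceed ncol(X)")
  rows <- lapply(dims, function(d) {
    Xd <- pca_reduce(X, d)
    uniform <- rep(PN, d)
    g_uni <- chunkify_graph(normalise_with_pv(Xd, uniform), uniform)
    pv <- compute_partition_vector(Xd, PN)$PV
    g_ada <- chunkify_graph(normalise_with_pv(Xd, pv), pv)
    data.frame(dims = d, dense_cells = as.numeric(PN)^d,
               graph_nodes = g_uni$V, adaptive_nodes = g_ada$V)
  })
  do.call(rbind, rows)
}

#' Runtime scaling with sample size
#'
#' Times SBM and ISBM fits on generated datasets of increasing size and
#' reports, for each step, the ratio of consecutive runtimes next to the
#' ratio of sample sizes. For an algorithm scaling linearly in `n` the time
#' ratio tracks the size ratio; a doubling of `n` increasing time by less
#' than a factor of 4 rules out quadratic growth. Absolute seconds are
#' hardware-dependent and deliberately not part of any contract.
#'
#' @param generator dataset generator; currently `"uo"` (the
#'   Unbalance-Overlapping composition rescaled to each size).
#' @param sizes increasing integer sample sizes.
#' @param seed integer seed used for the generated datasets.
#' @param PN partitioning number used for both algorithms (held fixed across
#'   sizes so only `n` varies).
#' @param threshold minimum chunk count to seed a cluster.
#' @param algorithms subset of `c("sbm", "isbm")` to time.
#' @param repeats each timing is the best of this many runs (default 3), to
#'   damp scheduler noise.
#' @return data frame with one row per size: `n`, `time_<algo>` (seconds,
#'   monotonic clock) and `ratio_<algo>` / `ratio_n` relative to the
#'   previous row.
#' @export
scaling_probe <- function(generator = "uo", sizes, seed = 1L, PN = 25L,
                          threshold = 5L, algorithms = c("sbm", "isbm"),
                          repeats = 3L) {
  if (!identical(generator, "uo"))
    param_error(sprintf("unknown generator '%s'", generator))
  sizes <- vapply(sizes, check_count, integer(1), arg = "sizes", min = 10L)
  if (is.unsorted(sizes, strictly = TRUE))
    param_error("`sizes` must be strictly increasing")
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  repeats <- check_count(repeats, "repeats", min = 1L)
  time_once <- function(f) {
    min(vapply(seq_len(repeats), function(i) {
      t0 <- proc.time()[["elapsed"]]
      f()
      proc.time()[["elapsed"]] - t0
    }, numeric(1)))
  }
  rows <- lapply(sizes, function(n) {
    cloud <- generate_uo_scaled(n, seed = seed)
    row <- data.frame(n = n)
    if ("sbm" %in% algorithms)
      row$time_sbm <- time_once(function() sbm_fit(cloud$points, PN, threshold))
    if ("isbm" %in% algorithms)
      row$time_isbm <- time_once(function() isbm_fit(cloud$points, PN, threshold))
    row
  })
  out <- do.call(rbind, rows)
  out$ratio_n <- c(NA, out$n[-1] / out$n[-nrow(out)])
  for (algo in algorithms) {
    tc <- out[[paste0("time_", algo)]]
    out[[paste0("ratio_", algo)]] <- c(NA, tc[-1] / pmax(tc[-length(tc)], 1e-6))
  }
  out
}

# ---- roster -----------------------------------------------------------------

# Fit one roster algorithm; returns list(labels, noise_label or NULL).
fit_algorithm <- function(name, X, params, seed) {
  params <- if (is.null(params)) list() else params
  switch(name,
    sbm = {
      fit <- sbm_fit(X, PN = params$pn %||% suggest_pn(X),
                     threshold = params$threshold %||% 5L)
      list(labels = fit$labels, noise_label = 0L)
    },
    isbm = {
      fit <- isbm_fit(X, PN = params$pn %||% suggest_pn(X),
                      threshold = params$threshold %||% 5L)
      list(labels = fit$labels, noise_label = -1L)
    },
    kmeans = {
      k <- params$k %||% param_error("kmeans needs `k` in its roster entry")
      km <- with_local_seed(seed, stats::kmeans(X, centers = k, nstart = 10L))
      list(labels = km$cluster, noise_label = NULL)
    },
    agglomerative = {
      k <- params$k %||% param_error("agglomerative needs `k` in its roster entry")
      hc <- stats::hclust(stats::dist(X), method = params$linkage %||% "ward.D2")
      list(labels = stats::cutree(hc, k = k), noise_label = NULL)
    },
    fcm = {
      k <- params$k %||% param_error("fcm needs `k` in its roster entry")
      cm <- with_local_seed(seed, e1071::cmeans(X, centers = k))
      list(labels = cm$cluster, noise_label = NULL)
    },
    param_error(sprintf("unknown algorithm '%s' in the roster", name))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

benchmark_dataset <- function(dataset, seed) {
  if (!is.null(dataset$file)) {
    pc <- read_point_cloud(dataset$file,
                           delimiter = dataset$delimiter %||% ",",
                           label_column = dataset$label_column)
    if (is.null(pc$labels))
      param_error("benchmark dataset file must carry ground-truth labels")
    return(list(points = pc$points, labels = pc$labels))
  }
  gen <- dataset$generator %||% "uo"
  if (identical(gen, "uo")) {
    cloud <- generate_uo(seed = seed, sd = dataset$sd %||% 1.0)
  } else if (identical(gen, "mixture")) {
    cloud <- generate_mixture(dataset$specs, seed = seed)
  } else {
    param_error(sprintf("unknown generator '%s'", gen))
  }
  list(points = cloud$points, labels = cloud$labels)
}

#' Run a clustering benchmark
#'
#' For each repetition (re-seeded deterministically as `seed + rep - 1`),
#' generates or loads the dataset, optionally PCA-reduces it, fits every
#' roster algorithm, scores the result with [metric_suite()] against the
#' ground truth, and averages the scores over repetitions. A roster entry
#' whose fit fails is recorded as a missing row and the run continues;
#' an unknown algorithm name is a configuration error.
#'
#' @param config a list (or path to a YAML file) with fields:
#'   `dataset` (either `generator`/`sd`/`specs` or `file`/`label_column`),
#'   `roster` (named list of per-algorithm parameter lists; names from
#'   `sbm`, `isbm`, `kmeans`, `agglomerative`, `fcm`), `seed`,
#'   `repetitions`, optional `pca_dims` and `exclude_noise`.
#' @return object of class `benchmark_report`: `scores` (one row per
#'   algorithm and metric, averaged, scaled by 100), `chunk_stats` (dense
#'   cells vs graph nodes at the data's dimensionality, when the roster
#'   contains a grid algorithm), `failures`, and a `provenance` block
#'   (config, seeds, package/R versions) sufficient to regenerate the
#'   report bit-identically.
#' @examples
#' cfg <- list(dataset = list(generator = "uo"),
#'             roster = list(isbm = list(pn = 30)),
#'             seed = 1, repetitions = 1)
#' run_benchmark(cfg)
#' @export
run_benchmark <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config$roster) || length(config$roster) == 0L ||
      is.null(names(config$roster)) || any(names(config$roster) == ""))
    param_error("`config$roster` must be a non-empty named list")
  reps <- check_count(config$repetitions %||% 1L, "repetitions", min = 1L)
  seed <- check_count(config$seed %||% 1L, "seed", min = 0L)
  roster <- names(config$roster)
  known <- c("sbm", "isbm", "kmeans", "agglomerative", "fcm")
  bad <- setdiff(roster, known)
  if (length(bad) > 0L)
    param_error(sprintf("unknown algorithm%s in the roster: %s",
                        if (length(bad) > 1L) "s" else "",
                        paste(bad, collapse = ", ")))

  acc <- list()
  failures <- character(0)
  chunk_stats <- NULL
  for (r in seq_len(reps)) {
    seed_r <- seed + r - 1L
    data <- benchmark_dataset(config$dataset %||% list(), seed_r)
    X <- data$points
    if (!is.null(config$pca_dims)) X <- pca_reduce(X, config$pca_dims)
    for (algo in roster) {
      res <- tryCatch(
        fit_algorithm(algo, X, config$roster[[algo]], seed_r),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("rep %d, %s: %s", r, algo,
                                        conditionMessage(res)))
        next
      }
      suite <- metric_suite(data$labels, res$labels,
                            noise_label = res$noise_label,
                            exclude_noise = isTRUE(config$exclude_noise))
      acc[[length(acc) + 1L]] <- data.frame(rep = r, algorithm = algo,
                                            metric = suite$metric,
                                            scaled = suite$scaled)
    }
    if (r == 1L && any(c("sbm", "isbm") %in% roster)) {
      grid_algo <- intersect(c("isbm", "sbm"), roster)[1L]
      pn <- config$roster[[grid_algo]]$pn %||% suggest_pn(X)
      chunk_stats <- chunk_statistics(X, PN = pn, dims = ncol(X))
    }
  }
  if (length(acc) == 0L) param_error("every roster fit failed; nothing to report")
  long <- do.call(rbind, acc)
  scores <- stats::aggregate(scaled ~ algorithm + metric, data = long, FUN = mean)
  scores <- scores[order(match(scores$algorithm, roster),
                         match(scores$metric,
                               c("ARI", "AMI", "Purity", "FMI", "VM", "SCS"))), ]
  rownames(scores) <- NULL
  structure(list(
    scores = scores,
    chunk_stats = chunk_stats,
    failures = failures,
    provenance = list(config = config, seed = seed, repetitions = reps,
                      seeds_used = seed + seq_len(reps) - 1L,
                      package_version = as.character(utils::packageVersion("sbmclust")),
                      r_version = R.version.string)
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report (scores x100, averaged over",
      x$provenance$repetitions, "repetition(s))\n")
  wide <- stats::reshape(x$scores, idvar = "algorithm", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^scaled\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  if (!is.null(x$chunk_stats)) {
    cat("\nChunk statistics (first repetition):\n")
    print(x$chunk_stats, row.names = FALSE)
  }
  if (length(x$failures) > 0L) {
    cat("\nFailed fits:\n")
    for (f in x$failures) cat(" -", f, "\n")
  }
  invisible(x)
}
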