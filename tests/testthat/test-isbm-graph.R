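test_that("partition vector scales with normalised variance, clamped to [2, PN]", {
  expect_equal(sbmclust:::pv_from_variances(c(0.04, 0.01), 20), c(20L, 5L))
  expect_equal(sbmclust:::pv_from_variances(rep(0.1, 3), 25), c(25L, 25L, 25L))
  expect_equal(sbmclust:::pv_from_variances(c(0.09, 0.0001), 10), c(10L, 2L))

  # from data: a 0/1 column has normalised population variance 1/4
  X <- cbind(rep(c(0, 1), each = 50),            # var 0.25 -> ratio 1 -> PN
             rep(c(0, 0.2, 1, 1), 25))           # smaller variance
  spec <- compute_partition_vector(X, PN = 20)
  expect_equal(spec$PV[1], 20L)
  expect_true(spec$PV[2] >= 2L && spec$PV[2] <= 20L)
  expect_error(compute_partition_vector(matrix(1, 5, 2), PN = 10),
               class = "sbmclust_degenerate_error")
})

test_that("per-dimension normalisation maps endpoints and midpoints onto [0, PV_d]", {
  expect_equal(normalise_with_pv(rbind(c(0, 0), c(10, 10)), PV = c(4, 2)),
               rbind(c(0, 0), c(4, 2)))
  X <- matrix(rnorm(60), ncol = 3)
  expect_equal(normalise_with_pv(X, PV = rep(7, 3)), minmax_normalise(X, 7))
  mid <- rbind(c(0, 0), c(1, 2), c(2, 4))  # midpoints of both ranges
  expect_equal(normalise_with_pv(mid, PV = c(6, 8))[2, ], c(3, 4))
})

test_that("graph chunkification stores only occupied chunks with exact counts", {
  one <- chunkify_graph(matrix(0.4, nrow = 20, ncol = 2), PV = c(3, 3))
  expect_equal(one$V, 1L)
  expect_equal(one$count, 20L)

  # every point its own chunk: V reaches its n bound
  diag_pts <- cbind(seq(0.5, 7.5), seq(0.5, 7.5))
  worst <- chunkify_graph(diag_pts, PV = c(8, 8))
  expect_equal(worst$V, 8L)
  expect_true(all(worst$count == 1L))

  pts <- rbind(c(0.1, 0.1), c(1.5, 1.5), c(1.6, 1.4))
  g <- chunkify_graph(pts, PV = c(2, 2))
  expect_equal(g$V, 2L)
  expect_setequal(g$keys, c("0_0", "1_1"))
  expect_equal(g$count[match("1_1", g$keys)], 2L)
  expect_equal(sum(g$count), 3L)
  expect_true(all(g$label == 0L) && all(g$visited == 0L))
})

test_that("neighbourhoods are diagonal-inclusive and respect grid bounds", {
  corner <- chunk_neighbours(c(0, 0), PV = c(5, 5))
  expect_equal(nrow(corner), 3L)
  expect_setequal(apply(corner, 1, paste, collapse = ","),
                  c("0,1", "1,0", "1,1"))
  expect_equal(nrow(chunk_neighbours(c(2, 2), PV = c(5, 5))), 8L)
  expect_equal(nrow(chunk_neighbours(c(1, 1, 1), PV = c(4, 4, 4))), 26L)
  expect_error(chunk_neighbours(c(5, 0), PV = c(5, 5)),
               class = "sbmclust_param_error")
})

test_that("graph centroid search matches the array version on a shared grid", {
  single <- chunkify_graph(matrix(rep(0.1, 12), ncol = 2), PV = c(3, 3))
  got <- find_centroids_graph(single, threshold = 5)
  expect_equal(nrow(got), 1L)

  two <- chunkify_graph(points_from_counts(c(5, 3)), PV = 2L)
  expect_error(chunkify_graph(points_from_counts(c(5, 3)), PV = 1L),
               class = "sbmclust_param_error")
  cands <- find_centroids_graph(two, threshold = 0)
  expect_equal(unname(cands[, 1]), 0L)

  set.seed(7)
  for (case in 1:10) {
    n <- sample(100:800, 1)
    N <- sample(1:3, 1)
    pn <- sample(3:10, 1)
    X <- matrix(rnorm(n * N), n, N)
    Xn <- minmax_normalise(X, pn)
    arr <- find_centroids_array(chunkify_array(Xn, pn), threshold = 1)
    gra <- find_centroids_graph(chunkify_graph(Xn, rep(pn, N)), threshold = 1)
    expect_equal(unname(gra), unname(arr))
  }
})

test_that("graph expansion equals array expansion and cannot cross empty space", {
  # same 1-D cases as the array tests
  g <- chunkify_graph(points_from_counts(c(4, 1, 5)), PV = 3L)
  g <- expand_graph(g, find_centroids_graph(g, threshold = 0))
  labs <- g$label[match(c("0", "1", "2"), g$keys)]
  expect_equal(labs, c(2L, 1L, 1L))
  expect_true(all(g$visited[g$label > 0L] == 1L))

  # disconnected occupied regions: one cluster each, BFS cannot bridge the gap
  g2 <- chunkify_graph(points_from_counts(c(6, 2, 0, 0, 7, 3)), PV = 6L)
  g2 <- expand_graph(g2, find_centroids_graph(g2, threshold = 0))
  expect_equal(g2$n_clusters, 2L)
  expect_equal(sum(g2$label == 0L), 0L)

  # an unreached node keeps the noise label
  g3 <- chunkify_graph(points_from_counts(c(9, 0, 1)), PV = 3L)
  g3 <- expand_graph(g3, find_centroids_graph(g3, threshold = 3))
  expect_equal(g3$label[match("2", g3$keys)], 0L)
})

test_that("isbm_fit recovers well-separated mixtures with the 0-based/-1 convention", {
  cloud <- generate_mixture(list(
    list(center = c(0, 0), size = 300, sd = 1),
    list(center = c(15, 0), size = 200, sd = 1),
    list(center = c(7, 14), size = 250, sd = 1)), seed = 9)
  fit <- isbm_fit(cloud$points, PN = 15, threshold = 1)
  expect_equal(fit$n_clusters, 3L)
  expect_equal(fit$noise_label, -1L)
  expect_true(all(fit$labels %in% c(-1L, 0L, 1L, 2L)))
  oracle <- nearest_centre(cloud$points, list(c(0, 0), c(15, 0), c(7, 14)))
  expect_gte(majority_accuracy(fit$labels, oracle, noise_label = -1L), 0.99)
  expect_identical(fit$labels, isbm_fit(cloud$points, PN = 15, threshold = 1)$labels)
})

test_that("uniform partitioning reproduces the array pipeline up to the label shift", {
  set.seed(31)
  for (case in 1:15) {
    n <- sample(100:1000, 1)
    N <- sample(1:3, 1)
    pn <- sample(3:12, 1)
    X <- matrix(rnorm(n * N), n, N)
    a <- sbm_fit(X, pn, threshold = 3)
    b <- isbm_fit(X, pn, threshold = 3, pv = rep(pn, N))
    expect_true(same_partition(a$labels, 0L, b$labels, -1L))
    expect_identical(a$labels - 1L, b$labels)  # same deterministic numbering
  }
})

test_that("graph node count never exceeds the sample count or the cell count", {
  set.seed(13)
  for (case in 1:15) {
    n <- sample(20:2000, 1)
    N <- sample(1:4, 1)
    pn <- sample(2:20, 1)
    X <- matrix(rnorm(n * N), n, N)
    pv <- compute_partition_vector(X, pn)$PV
    g <- chunkify_graph(normalise_with_pv(X, pv), pv)
    expect_lte(g$V, n)
    expect_lte(g$V, prod(pv))
    expect_equal(sum(g$count), n)
  }
})

test_that("adaptive partitioning stores no more nodes than uniform partitioning", {
  cloud <- generate_uo(seed = 3)
  X <- cbind(cloud$points, 0.1 * rnorm(4300))   # a low-variance third feature
  pn <- 25L
  uni <- chunkify_graph(minmax_normalise(X, pn), rep(pn, 3L))
  pv <- compute_partition_vector(X, pn)$PV
  ada <- chunkify_graph(normalise_with_pv(X, pv), pv)
  expect_lte(ada$V, uni$V)
})

test_that("the partitioning-number suggestion follows n times max variance over 10", {
  # 0/1 balanced feature: normalised population variance exactly 1/4
  X <- cbind(rep(c(0, 1), 500), rnorm(1000, sd = 0.01))
  expect_equal(suggest_pn(X), 25L)
  # tiny dataset rounds below the floor and clamps to 2
  X_small <- cbind(c(rep(0, 38), 1, 1), rnorm(40, sd = 0.001))
  expect_equal(suggest_pn(X_small), 2L)
  # linear in n at fixed variance (pre-clamp)
  X10 <- cbind(rep(c(0, 1), 5000), rnorm(10000, sd = 0.01))
  expect_equal(suggest_pn(X10, cap = 500L), 250L)
  expect_error(suggest_pn(matrix(3, 4, 2)), class = "sbmclust_degenerate_error")
})
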