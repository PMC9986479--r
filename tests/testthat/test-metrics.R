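test_that("spike cluster score matches its defining formula on worked cases", {
  expect_equal(as.numeric(spike_cluster_score(c(0, 0, 1, 1), c(5, 5, 7, 7))), 1)
  expect_equal(as.numeric(spike_cluster_score(c(0, 0, 1), singleton_labeling(3))), 1)
  # T0: dominant label 0 has 3 of its 4 global occurrences inside -> 3/4;
  # T1: dominant label 1 entirely inside -> 2/2; unweighted mean 0.875
  expect_equal(as.numeric(
    spike_cluster_score(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 0, 1, 1))), 0.875)
  breakdown <- attr(
    spike_cluster_score(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 0, 1, 1)), "breakdown")
  expect_equal(unname(breakdown), c(0.75, 1))
  # annexing points of another true cluster is punished; splitting is not
  split_pred <- c(3, 3, 7, 7, 1, 1)
  expect_equal(as.numeric(spike_cluster_score(c(0, 0, 0, 0, 1, 1), split_pred)), 1)
})

test_that("a fully noise-predicted true cluster scores zero with a warning", {
  expect_warning(
    s <- spike_cluster_score(c(0, 0, 1, 1), c(0, 0, -1, -1), noise_label = -1L),
    "noise")
  expect_equal(as.numeric(s), 0.5)
})

test_that("removing noise-predicted points never changes the spike cluster score", {
  truth <- c(0, 0, 0, 1, 1, 2)
  pred <- c(4, 4, -1, 5, -1, 6)
  expect_true(scs_noise_invariance_check(truth, pred, noise_label = -1L))
  expect_true(scs_noise_invariance_check(truth, c(1, 1, 1, 2, 2, 3), noise_label = -1L))
  set.seed(2024)
  for (case in 1:100) {
    pair <- random_label_pair(n = sample(10:60, 1))
    expect_true(scs_noise_invariance_check(pair$truth, pair$pred, noise_label = -1L))
    keep <- pair$pred != -1L
    full <- spike_cluster_score(pair$truth, pair$pred, noise_label = -1L)
    reduced <- spike_cluster_score(pair$truth[keep], pair$pred[keep],
                                   noise_label = -1L)
    expect_equal(as.numeric(full), as.numeric(reduced))
  }
})

test_that("purity matches its definition and rewards singleton overclustering", {
  expect_equal(purity(c(0, 1, 0, 1, 2), singleton_labeling(5)), 1)
  expect_equal(purity(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(purity(c(0, 0, 1, 1), c(0, 0, 0, 1)), 0.75)
})

test_that("scores agree with the brute-force oracles on exhaustive small instances", {
  # every (truth, prediction) pair over 3 points and up to 3 labels
  combos3 <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  for (i in seq_len(nrow(combos3))) {
    for (j in seq_len(nrow(combos3))) {
      truth <- combos3[i, ]
      pred <- combos3[j, ]
      expect_equal(as.numeric(spike_cluster_score(truth, pred)),
                   scs_oracle(truth, pred))
      expect_equal(purity(truth, pred), purity_oracle(truth, pred))
    }
  }
  # all predictions over 6 points against representative truths, with noise
  combos6 <- as.matrix(expand.grid(rep(list(c(-1, 0, 1, 2)), 3)))
  truths <- list(c(0, 0, 0, 1, 1, 2), c(0, 1, 2, 0, 1, 2), rep(0, 6))
  for (truth in truths) {
    for (j in seq_len(nrow(combos6))) {
      pred <- c(combos6[j, ], 2, 0, 1)
      expect_equal(
        suppressWarnings(as.numeric(spike_cluster_score(truth, pred,
                                                        noise_label = -1L))),
        scs_oracle(truth, pred, noise = -1L))
      expect_equal(purity(truth, pred), purity_oracle(truth, pred))
    }
  }
})

test_that("scores are invariant to bijective relabelling", {
  set.seed(5)
  for (case in 1:20) {
    pair <- random_label_pair(n = 40, noise_frac = 0)
    perm_t <- sample(100:200)[seq_len(max(pair$truth) + 1L)]
    perm_p <- sample(300:400)[seq_len(max(pair$pred) + 1L)]
    expect_equal(as.numeric(spike_cluster_score(pair$truth, pair$pred)),
                 as.numeric(spike_cluster_score(perm_t[pair$truth + 1L],
                                                perm_p[pair$pred + 1L])))
    expect_equal(purity(pair$truth, pair$pred),
                 purity(perm_t[pair$truth + 1L], perm_p[pair$pred + 1L]))
  }
})

test_that("splitting a pure predicted cluster never lowers the spike cluster score", {
  set.seed(17)
  for (case in 1:30) {
    pair <- random_label_pair(n = 50, noise_frac = 0)
    # pick a predicted cluster lying entirely inside one true cluster
    target_true <- sample(unique(pair$truth), 1)
    inside <- which(pair$truth == target_true)
    pure_label <- max(pair$pred) + 1L
    pair$pred[inside] <- pure_label
    before <- as.numeric(spike_cluster_score(pair$truth, pair$pred))
    split <- pair$pred
    half <- inside[seq_len(ceiling(length(inside) / 2))]
    split[half] <- pure_label + 1L
    after <- as.numeric(spike_cluster_score(pair$truth, split))
    expect_gte(after, before - 1e-12)
  }
})

test_that("conventional indices match scikit-learn reference values", {
  # frozen cross-check values computed with scikit-learn 1.9.0
  cases <- list(
    list(t = c(0, 0, 0, 1, 1, 2, 2, 2, 2), p = c(1, 1, 2, 2, 2, 0, 0, 0, 1),
         ari = 0.357142857143, ami = 0.408670509722,
         fmi = 0.527046276695, vm = 0.589509827447),
    list(t = c(0, 0, 1, 1, 2, 2), p = c(0, 1, 0, 1, 0, 1),
         ari = -0.363636363636, ami = -0.448188687256, fmi = 0, vm = 0),
    list(t = c(rep(0, 5), rep(1, 3), rep(2, 2)), p = c(0, 0, 0, 0, 1, 1, 1, 2, 2, 2),
         ari = 0.460431654676, ami = 0.466656778282,
         fmi = 0.617213399848, vm = 0.611497108003)
  )
  for (cs in cases) {
    expect_equal(ari_score(cs$t, cs$p), cs$ari, tolerance = 1e-9)
    expect_equal(ami_score(cs$t, cs$p), cs$ami, tolerance = 1e-9)
    expect_equal(fmi_score(cs$t, cs$p), cs$fmi, tolerance = 1e-9)
    expect_equal(v_measure(cs$t, cs$p), cs$vm, tolerance = 1e-9)
  }
})

test_that("the metric suite scales by 100 and excludes noise only for conventional metrics", {
  perfect <- metric_suite(c(0, 0, 1, 1, 2), c(5, 5, 3, 3, 9))
  expect_equal(perfect$scaled, rep(100, 6))

  # near-zero ARI for independent labels at large n
  set.seed(8)
  t_big <- sample(0:3, 5000, replace = TRUE)
  p_big <- sample(0:3, 5000, replace = TRUE)
  expect_lt(abs(metric_suite(t_big, p_big)$raw[1]), 0.02)

  truth <- c(0, 0, 0, 1, 1, 1, 2, 2)
  pred <- c(4, 4, -1, 5, 5, -1, 6, 6)
  with_noise <- metric_suite(truth, pred, noise_label = -1L, exclude_noise = FALSE)
  without_noise <- metric_suite(truth, pred, noise_label = -1L, exclude_noise = TRUE)
  ari_row <- function(df) df$raw[df$metric == "ARI"]
  scs_row <- function(df) df$raw[df$metric == "SCS"]
  expect_false(isTRUE(all.equal(ari_row(with_noise), ari_row(without_noise))))
  expect_equal(scs_row(with_noise), scs_row(without_noise))
})
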