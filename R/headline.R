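# The headline evaluation protocol on the Unbalance-Overlapping benchmark:
# for each seed, generate the dataset, pick the partitioning number by an
# exploratory search around the suggested value (scored by ARI against the
# generator's ground truth, as when parametrising per dataset), and score
# the winning fit. Reported as means over seeds, scaled by 100.

#' Headline ISBM scores on the Unbalance-Overlapping benchmark
#'
#' Runs the full evaluation protocol for the UO dataset: per seed, generate
#' the 4,300-point six-cluster mixture, select the partitioning number by an
#' exploratory ARI-scored search over `pn_grid` (default: a window around
#' [suggest_pn()]), fit [isbm_fit()], and compute ARI and Spike Cluster
#' Score against the ground truth (all points, noise included). Returns the
#' per-seed table and the mean scores scaled by 100.
#'
#' @param seeds integer vector of generator seeds to average over.
#' @param sd isotropic cluster standard deviation of the generator
#'   (default 1).
#' @param threshold minimum chunk count to seed a cluster.
#' @param pn_grid optional integer vector of candidate partitioning numbers.
#' @return list with `per_seed` (data frame: seed, PN, ari, scs, raw scale)
#'   and `mean_ari` / `mean_scs` (scaled by 100).
#' @export
uo_headline <- function(seeds = 1:30, sd = 1.0, threshold = 5L, pn_grid = NULL) {
  rows <- lapply(seeds, function(s) {
    cloud <- generate_uo(seed = s, sd = sd)
    tuned <- tune_pn(cloud$points, cloud$labels, pn_grid = pn_grid,
                     threshold = threshold, metric = "ari")
    fit <- tuned$fit
    data.frame(seed = s, PN = tuned$PN,
               ari = ari_score(cloud$labels, fit$labels),
               scs = as.numeric(suppressWarnings(
                 spike_cluster_score(cloud$labels, fit$labels,
                                     noise_label = -1L))))
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       mean_ari = 100 * mean(per_seed$ari),
       mean_scs = 100 * mean(per_seed$scs))
}
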