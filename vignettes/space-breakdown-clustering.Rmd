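---
title: "Grid- and graph-based density clustering for spike sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid- and graph-based density clustering for spike sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmclust)
```

## The model

Spike-sorting feature spaces carry clusters that are imbalanced (firing
rates differ wildly), overlapping (drift and waveform similarity), and
numerous in points. The clustering approach implemented here assumes one
thing about a cluster: it is a **unimodal bump in point density**. Both
variants estimate density with a histogram over a regular grid and declare
each strict local maximum of that histogram the core of one cluster.

The original algorithm (`sbm_fit()`) runs five deterministic stages:

1. **Normalisation.** Each feature is min-max mapped onto `[0, PN]`,
   `x' = PN (x − min)/(max − min)`. Min-max is used (rather than a z-score)
   precisely because it lands every feature in a chosen range that is then
   trivially split into `PN` unit-width *chunks*. The cost is sensitivity
   to outliers: a single extreme point stretches the range and compresses
   everything else, so gross outliers should be removed upstream.
2. **Chunkification.** Each point's chunk is the floor of its normalised
   coordinates, and each of the `PN^N` chunks stores its point count.
3. **Centroid search.** A chunk is a seed candidate when its count
   (a) exceeds the minimum `threshold` and (b) strictly exceeds the count
   of every neighbour, neighbours being all chunks within one index step in
   every dimension (diagonal-inclusive, at most `3^N − 1`).
4. **Expansion.** Candidates are processed in descending-count order (ties:
   ascending lexicographic coordinate). From each, a breadth-first search
   claims any unlabelled, occupied neighbour whose count does not exceed
   the count of the chunk it is reached from — clusters only flow
   *downhill* from their density peak, and two peaks separated by a valley
   stay separate because the climb out of the valley is forbidden.
5. **Dechunkification.** Points inherit their chunk's label; chunks never
   claimed are noise. The original convention labels clusters from 1 and
   noise 0.

The improved variant (`isbm_fit()`) keeps these semantics and changes the
data structure and the resolution policy:

* **Sparse chunk graph.** Only occupied chunks are stored, as nodes
  `{count, label, visited}` keyed by their coordinates; adjacency is
  resolved by coordinate arithmetic. The node count `V` is bounded by both
  the sample count `n` (the worst case is every point alone in its chunk)
  and the number of cells, so memory is `O(n)` instead of `O(PN^N)`, and
  centroid search touches `V` nodes instead of `PN^N` cells. Expansion
  still probes up to `3^N − 1` neighbour keys per node, so the
  dimensionality cost has moved from memory into that factor; no further
  mitigation is attempted.
* **Partitioning vector.** `PN` becomes the *maximum* partitions per
  dimension. Per-feature variances are computed on `[0,1]`-normalised data
  (so they are comparable), divided by the largest, and each feature `d`
  receives `PV_d = ⌈PN · var_d / max_var⌉` partitions, clamped to
  `[2, PN]`. Low-information features are sliced coarsely, which removes
  spurious fragmentation along them and shrinks the graph further.
* **Labelling.** Clusters from 0 and noise −1.

With a uniform partitioning vector the two variants produce the identical
point partition (the test suite checks this on hundreds of random
datasets, including identical cluster numbering); the improvements change
cost, not semantics.

## Parameters

* **`PN`** (no default; the one required parameter). Chunk width in
  normalised units is `range/PN` per feature, so `PN` is a bandwidth: too
  coarse merges close clusters, too fine fragments a cluster into several
  local maxima (overclustering) and eventually starves every chunk below
  the threshold. `suggest_pn()` implements the estimate
  `PN = round(n · max_var/10)` (max normalised variance), which is a
  starting point only; `tune_pn()` automates the recommended exploratory
  search around it when reference labels exist.
* **`threshold`** (default 5 points). A seed candidate must *exceed* this
  count; it exists to stop small conglomerations of isolated noise points
  from crowning their own cluster. The default is deliberately small
  relative to the thousands of points of a typical recording; with very
  small datasets, lower it.
* **`cell_budget`** (dense variant only, default `1e7` cells, option
  `sbmclust.cell_budget`). `sbm_fit()` refuses to allocate a dense array
  beyond the budget rather than exhausting memory; `isbm_fit()` has no such
  limit by construction.

## The Spike Cluster Score

For each unique true label `T_i`, let `P_j` be the most frequent non-noise
predicted label among the points of `T_i`; then
`Score(T_i) = count(P(T_i) = P_j) / count(P = P_j)` — the fraction of all
of `P_j`'s occurrences that fall inside `T_i` — and the overall score is
the unweighted mean over unique true labels. Three consequences, each
property-tested:

* splitting a predicted cluster that lies inside one true cluster never
  lowers the score (overclustering tolerance, the design goal);
* annexing points of other true clusters dilutes `P_j` everywhere and is
  punished — underclustering costs, which plain Purity barely registers;
* noise predictions are ineligible as `P_j`, which is exactly the reading
  under which deleting noise-predicted points provably leaves the score
  unchanged. The one undefined corner is a true cluster predicted entirely
  as noise: it contributes 0, with a warning, and is the only case in
  which `scs_noise_invariance_check()` can fail.

Ties for "most frequent" are resolved in favour of the candidate giving
the higher score, then the smallest label — the most charitable
deterministic reading. The mean over true labels is unweighted, so a
50-point cluster counts as much as a 1,250-point one. Purity is
implemented from its definition (largest single-truth overlap of each
predicted cluster, summed, over `n`); ARI is delegated to
`mclust::adjustedRandIndex()`; AMI, FMI and V-measure are computed from
the contingency table by their standard formulas (no installed R package
provides them) and are cross-checked in the tests against frozen
scikit-learn reference values.

## Numerical and design choices

Where the procedure leaves details open, this package fixes them as
follows (all are contract, not accident, and the tests pin them):

* **Upper-edge clamp.** A normalised coordinate exactly equal to its
  extent floors into the last chunk (otherwise the index overflows).
* **Strict maxima and plateaus.** Candidacy uses a strict `>` over all
  neighbours, taken literally; a count-equal plateau therefore produces no
  candidate inside it. The alternative (`≥` with tie-breaking) would crown
  every plateau cell; strictness is the conservative reading.
* **Determinism.** Candidate processing order (descending count, then
  ascending lexicographic coordinate) and a fixed neighbour-offset
  enumeration shared by both pipelines decide which cluster claims a
  contested chunk; repeated runs are bit-identical.
* **Merging.** If an expansion reaches a not-yet-processed candidate and
  the downhill condition holds, that candidate is absorbed rather than
  seeding its own cluster. Under strict candidacy this cannot actually
  trigger — a strict local maximum exceeds every neighbour, so it can
  never be entered downhill — but the rule is kept because the procedure
  it implements explicitly allows candidates to merge during expansion.
* **Variance.** Population form (divide by `n`), immaterial after the
  ratio-to-maximum but fixed for reproducibility. Partition counts round
  *up* with a floor of 2: a single-partition dimension would carry no
  spatial information, and rounding up errs toward resolution.
* **Graph keys.** Coordinates joined with `"_"`; any bijective, run-stable
  encoding would do.
* **Degenerate inputs.** A constant feature makes min-max normalisation
  undefined and raises an error naming the column (a one-point dataset is
  the extreme case); all-constant data cannot yield a partitioning vector.

## The synthetic generators

`generate_mixture()` draws exact per-cluster sizes from diagonal Gaussians
in spec order (block-ordered labels, one seeded RNG stream per call, no
global state touched). It emulates the *feature-space* structure the
method targets — imbalance, overlap, unimodal bumps — and nothing
upstream: no waveforms, no drift over time, no non-Gaussian or curved
clusters, no correlated noise. Passing tests on these mixtures therefore
show the mechanics are right under the method's own assumptions, not that
real tetrode data will score alike.

`generate_uo()` rebuilds the "Unbalance-Overlapping" benchmark
composition: 4,300 points, six clusters of 500/50/1000/1250/250/1250
points centred at (−2,0), (−2,3), (3,−2), (5,6), (4,−1), (1,−2). The
composition fixes sizes and centres but **not the spread**, which is
exposed as `sd` with a default of 1. That default is an honest unit
choice, and it matters: the three right-hand centres are only 1.4–2 units
apart, so at unit spread they fuse into one density ridge that no
label-free method can split — an exploratory search over `PN` tops out
near ARI ≈ 0.5–0.6 on these realisations (the acceptance script computes
the exact values), and even k-means given the true `k` does no better.
The same code recovers the composition nearly perfectly (ARI ≥ 0.95,
beating k-means) once the spread is ~0.3–0.4 units, i.e. when the
clusters are visibly distinct-but-overlapping. Headline scores on this
benchmark are therefore a statement about the chosen spread as much as
about the algorithm, which is why the spread is a visible parameter and
the reported numbers are always recomputed, never quoted.

## Problem sizes used in the checks

The shipped tests run the generators at their native sizes (UO at 4,300
points; separated mixtures at 2,000 points for cluster-count recovery
across `k = 2..6`), use 50–100 random datasets of up to 5,000 points and
6 dimensions for the space-bound and equivalence properties, exhaustive
enumeration up to 3 points/3 labels (plus sampled 6-point instances) for
the metric oracles, and runtime-scaling probes from 4,300 to 34,400
points, asserting only ratios — never absolute seconds. The headline UO
evaluation averages 30 seeded realisations with a per-seed exploratory
`PN` search.

## Known limitations

* Clusters are found as strict unimodal histogram peaks: genuinely
  multimodal or heavy-tailed clusters are split (by design — within spike
  sorting, split-then-merge beats mixing), and clusters thinner than one
  chunk can be absorbed or go to noise.
* The dense variant is memory-bound at `PN^N` cells and refuses beyond its
  budget; the graph variant removes storage but still enumerates `3^N − 1`
  neighbour keys per node, so very high dimensionality remains expensive.
* Min-max normalisation is outlier-sensitive; screen features first.
* The histogram bandwidth (`PN`) is global per feature; clusters of very
  different spread in the *same* feature share one resolution.
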