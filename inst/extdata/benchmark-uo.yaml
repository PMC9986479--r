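# Example benchmark configuration: the Unbalance-Overlapping generator with
# the full roster available in this package. Per-algorithm parameters are a
# starting point for this dataset (unverified against any published
# supplementary parametrisation); tune per dataset.
dataset:
  generator: uo
  sd: 1.0
seed: 1
repetitions: 3
exclude_noise: false
roster:
  isbm:
    pn: 30
    threshold: 5
  sbm:
    pn: 30
    threshold: 5
  kmeans:
    k: 6
  agglomerative:
    k: 6
    linkage: ward.D2
  fcm:
    k: 6
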