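# microCT-like run: high-contrast multi-region phantom segmented by model
# training. Filter set, supervoxel and training parameters follow the
# defaults documented for this regime, with scales matched to the 64-cube
# phantom (unit contrast between regions).
seed: 11
input:
  phantom:
    type: multiregion
    size: 64
    n_regions: 4
    contrast: 1
    noise_sd: 0.1
channels:
  - name: tv1
    operator: total_variation
    source: raw
    params: {lambda: 1, n_iter: 100}
  - name: gc1
    operator: gaussian_centering
    source: tv1
    params: {sigma: 2}
  - name: gn1
    operator: gaussian_normalization
    source: tv1
    params: {sigma: 2}
  - name: lg1
    operator: log
    source: tv1
    params: {sigma: 2, thresh: no, response: bright}
  - name: dg1
    operator: dog
    source: tv1
    params: {sigma_init: 2, sigma_ratio: 1.6}
supervoxels:
  source: tv1
  shape: [5, 5, 5]
  spacing: [1, 1, 1]
  compactness: 20
annotations:
  labels:
    - {name: background, color: "#2ca02c"}
    - {name: outer, color: "#1f77b4"}
    - {name: mid, color: "#9467bd"}
    - {name: core, color: "#d62728"}
  strokes:
    - {label: 1, mode: supervoxel, pen_width: 2,
       seeds: [[8, 3, 3], [8, 60, 60], [32, 3, 32], [32, 60, 3],
               [56, 3, 3], [56, 60, 60]]}
    - {label: 2, mode: supervoxel, pen_width: 2,
       seeds: [[32, 10, 32], [32, 32, 10], [32, 55, 32]]}
    - {label: 3, mode: supervoxel, pen_width: 2,
       seeds: [[32, 20, 32], [32, 32, 20], [32, 45, 32]]}
    - {label: 4, mode: supervoxel, pen_width: 2,
       seeds: [[32, 32, 32], [36, 30, 32]]}
train:
  sources: [tv1, gc1, gn1, lg1, dg1]
  classifier: ensemble_rf
  n_trees: 100
  refinement: appearance
  refine_lambda: 50
  confidence: 50
  rounds: 5
refine:
  - {label: 4, method: fill_holes, radius: 1}
  - {label: 4, method: opening, radius: 1}
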