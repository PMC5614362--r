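# cryoSXT-like run: medium-SNR phantom with many varied blob organelles,
# segmented semi-manually with super-regions (no model training, as in this
# regime), cleaned morphologically, then analysed with the label splitter.
# The phantom seed is fixed so the stroke coordinates (one per organelle,
# placed at the generative blob centers) stay valid.
seed: 31
input:
  phantom:
    type: organelle
    size: 64
    n_blobs: 12
    n_tubes: 0
    snr: 5
    seed: 1
channels:
  - name: tv4
    operator: total_variation
    source: raw
    params: {lambda: 0.5, n_iter: 100}
supervoxels:
  source: tv4
  shape: [5, 5, 5]
  spacing: [1, 1, 1]
  compactness: 30
annotations:
  labels:
    - {name: organelles, color: "#ff7f0e"}
  strokes:
    - {label: 1, mode: supervoxel, pen_width: 2,
       seeds: [[53, 18, 52], [18, 17, 42], [14, 21, 27], [32, 37, 32],
               [13, 43, 28], [34, 47, 9], [50, 29, 20], [40, 28, 53],
               [21, 31, 46], [46, 55, 29], [18, 43, 14], [39, 51, 46]]}
refine:
  - {label: 1, method: fill_holes, radius: 1, scope: all_slices_2d}
  - {label: 1, method: closing, radius: 1, scope: all_slices_2d}
  - {label: 1, method: dilation, radius: 1, scope: all_slices_2d}
split:
  labels: [1]
  query_channel: raw
  rules:
    - name: large
      color: "#d62728"
      rules:
        - {measure: volume_voxels, comparator: ">", value: 400}
    - name: small
      color: "#1f77b4"
      is_others: yes
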