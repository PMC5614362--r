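# cryoET-like run: low-SNR phantom with blob organelles and thin tubes.
# Demonstrates the layered filter set (Gaussian feeding total variation)
# and the super-region hierarchy; organelle supervoxels/megavoxels are the
# segmentation substrate, as in a super-region annotation session.
seed: 21
input:
  phantom:
    type: organelle
    size: 64
    n_blobs: 10
    n_tubes: 2
    snr: 3
channels:
  - name: g1
    operator: gaussian
    source: raw
    params: {sigma: 1}
  - name: tv2
    operator: total_variation
    source: g1
    params: {lambda: 0.5, n_iter: 100}
  - name: dg2
    operator: dog
    source: tv2
    params: {sigma_init: 2, sigma_ratio: 1.6}
  - name: st1
    operator: structure_tensor_det
    source: tv2
    params: {sigma1: 2, sigma_area: 2}
supervoxels:
  source: tv2
  shape: [5, 5, 5]
  spacing: [1, 1, 1]
  compactness: 50
megavoxels:
  source: tv2
  lambda_mv: 0.1
  num_bins: 50
  gamma: auto
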