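# srvox — super-region segmentation of volumetric bioimaging data

Segmenting 3D volumes from cryo electron tomography (cryoET), cryo soft
X-ray tomography (cryoSXT) or phase-contrast micro-tomography (microCT) by
hand takes days to weeks, and low signal-to-noise data make manually traced
boundaries subjective. srvox is a headless, scriptable R toolkit for
*semi-automatic* volume segmentation aimed at structural and cell
biologists who want reproducible segmentations driven by a few annotations
instead of exhaustive manual tracing.

The core idea is a two-tier **super-region hierarchy**. SLIC-style
clustering deforms a regular 3D seed grid toward image boundaries,
grouping the volume's voxels into a few thousand boundary-adherent
**supervoxels**: each voxel `v` joins the cluster minimizing

    D(v, c) = |I(v) − c_I| + (compactness/100) · ‖diag(spacing)·(v − c_s)/shape‖

Adjacent, similar supervoxels are then merged into **megavoxels** by greedy
agglomeration on the region adjacency graph, where two clusters merge when
their χ² histogram distance satisfies the Felzenszwalb scale test
`w ≤ min(Int(A) + λ/|A|, Int(B) + λ/|B|)`. Scribbles placed at supervoxel
or megavoxel granularity train a classifier (random forest by default) on
per-region descriptors; predictions are regularized by a Potts or
appearance-weighted Markov random field solved with iterated conditional
modes, and a confidence threshold on the top-two probability margin,
`(p₁ − p₂)·100 ≥ confidence`, decides which regions are promoted to
annotations each round. Segmented labels can finally be decomposed into
connected objects, measured (intensity, variance, volume, position) and
classified by user rules.

Feature channels (Gaussian, total variation, thresholding, local
centering/normalization, Laplacian of Gaussian, difference of Gaussians,
structure-tensor determinant), morphological cleanup, HDF5/MRC/TIFF I/O
and ground-truthed synthetic phantoms round out the pipeline so every
stage is testable without experimental data.

## Worked example

Segment a three-region phantom (noisy nested ellipsoids) from six
scribbles:

```r
library(srvox)

ph <- make_multiregion(size = 48, n_regions = 3, seed = 7)
ph
#> phantom 48x48x48, 3 truth classes, noise sd 0.1, seed 7

ws <- new_workspace(ph$volume)
compute_channel(ws, "tv", "total_variation",
                params = list(lambda = 1, n_iter = 100))
compute_supervoxels(ws, "tv", shape = c(5, 5, 5), compactness = 20)
#> supervoxel partition: 1000 regions over 48x48x48 (source 'tv')
compute_megavoxels(ws, "tv", lambda_mv = 0.1, num_bins = 20)
#> megavoxel partition: 151 regions from 1000 supervoxels

lvl <- add_level(ws)
for (nm in c("background", "shell", "core")) add_label(ws, lvl, nm)
annotate(ws, lvl, 1, rbind(c(6, 4, 4), c(42, 44, 44)),
         mode = "supervoxel", pen_width = 2)
annotate(ws, lvl, 2, rbind(c(24, 8, 24), c(24, 40, 24)),
         mode = "supervoxel", pen_width = 2)
annotate(ws, lvl, 3, matrix(c(24, 24, 24), 1),
         mode = "supervoxel", pen_width = 2)

cfg <- train_config(lvl, sources = "tv", refinement = "appearance",
                    refine_lambda = 50, confidence = 50, seed = 1)
iterate_training(ws, cfg, rounds = 5)

seg <- ws$levels[[as.character(lvl)]]$voxel_labels
round(dice_score(seg, ph$truth), 3)
#>     1     2     3
#> 0.996 0.988 0.948
```

The 48³ volume collapses to 1000 supervoxels and 151 megavoxels — three
orders of magnitude fewer decisions than voxel-wise labeling — and six
supervoxel scribbles are enough for the train → refine → commit loop to
recover each ground-truth region with a Dice overlap of about 0.95 or
better (1 = perfect agreement).

Complete pipelines can also be driven from a single YAML config
(`run_pipeline()`, or the `inst/scripts/srvox` command-line wrapper); three
bundled configs under `inst/configs/` reproduce the microCT-like,
cryoET-like and cryoSXT-like workflows end to end on matching phantoms.

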