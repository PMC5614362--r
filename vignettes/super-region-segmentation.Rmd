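---
title: "Super-region segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-region segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

srvox is a headless toolkit for semi-automatic segmentation of 3D scalar
volumes — tomograms from cryo electron tomography (cryoET), cryo soft X-ray
tomography (cryoSXT) or phase-contrast micro-tomography (microCT). Rather
than classifying voxels one by one, it works on a two-tier *super-region*
hierarchy: supervoxels (compact clusters of similar, adjacent voxels) and
megavoxels (conglomerates of similar, adjacent supervoxels). A handful of
user scribbles at super-region granularity then trains a classifier that
labels the rest of the volume, and confident predictions are promoted to
annotations iteratively. This document records the models, the parameters
that matter, and the design decisions taken where the procedure admitted
more than one reasonable choice.

## Feature channels

All downstream computation consumes *feature channels*: derived scalar
grids over the selected region of interest (ROI). Eight operators are
provided; each maps a source grid (the raw data or another channel) to a
grid of the same extent, so channels can be layered into filter sets (a
Gaussian channel feeding a total-variation channel is a common pair for
noisy data).

| operator | parameters (default) | purpose |
|---|---|---|
| gaussian | sigma (1) | isotropic denoising |
| total_variation | lambda (10), spacing (1,1,1), n_iter (100), clamp | edge-preserving denoising |
| threshold | vmin, vmax | binary in-range mask |
| gaussian_centering | sigma (2) | local mean removal |
| gaussian_normalization | sigma (2) | local z-score |
| log | sigma (2), thresh (no), response (bright) | blob detection |
| dog | sigma_init (2), sigma_ratio (1.6) | band-pass blob detection |
| structure_tensor_det | sigma1 (2), sigma_area (2) | texture/corner strength |

All sigmas are in voxels. Values inside the documented useful ranges (e.g.
sigma in [0.5, 10], TV lambda in [0.1, 30], 50–500 TV iterations) are
accepted silently; values outside warn but run.

Numerical choices:

* **Boundary handling** is reflect padding everywhere (periodic is
  available per call); reflection avoids edge artifacts on small ROIs.
* **Kernel truncation** at 4 sigma — the standard accuracy/cost tradeoff.
* The sampled second-derivative kernel is corrected to zero sum so that
  derivative-type operators map constant grids to exactly zero.
* **Total variation** uses the dual (projection) formulation of isotropic
  ROF denoising with a fixed step `tau = 1/(12 * max(spacing)^2)` (inside
  the 3D stability bound) and a fixed iteration count — no early stopping,
  so runs are reproducible by parameter record alone. `spacing` acts as
  per-axis gradient weights, i.e. it tunes how strongly boundaries in each
  direction are penalized; the isotropic (coupled-norm) variant is the
  default and only form. `clamp` truncates intensities *before* denoising,
  which is how contrast clamping is used in practice to suppress extreme
  values.
* **gaussian_normalization** divides by
  `sqrt(G((I - G(I))^2) + eps)` with `eps = 1e-8 * var(I)`, making the
  channel invariant to affine intensity rescalings of the input up to the
  epsilon guard.
* **LoG sign convention**: `response = "bright"` negates the operator so
  bright blobs score positive; `thresh = yes` zeroes negative responses
  after that convention is applied.

## Supervoxels

Supervoxels are computed by SLIC-style clustering. Seeds start on a
regular grid of cell size `shape = (sz, sy, sx)` (the product is capped at
1024), each perturbed to the lowest-gradient voxel in its 3×3×3
neighborhood so seeds avoid boundaries. Ten assignment/update iterations
minimize

```
D = |I(v) - c_I|  +  (compactness / 100) * || diag(spacing) (v - c_s) / shape ||
```

with intensities rescaled to [0, 1] first, so `compactness` values in the
usual [1, 200] range behave comparably across datasets: low compactness
lets regions deform toward image boundaries, high compactness keeps them
cuboidal. `spacing` weights the spatial distance per axis, emphasizing
boundary adherence in chosen directions. Ties in the assignment keep the
lowest region id; iteration order is fixed; there is no randomness, so
identical inputs give identical partitions.

A final connectivity pass relabels 6-connected fragments, absorbing any
fragment smaller than a quarter cell into the adjacent region discovered
just before it (raster order), which guarantees a total, dense, connected
partition.

## Megavoxels

Megavoxels merge adjacent, similar supervoxels by greedy agglomeration on
the region adjacency graph (RAG). Each supervoxel carries a `num_bins`-bin
normalized intensity histogram of the source channel; edge dissimilarity
is the chi-squared histogram distance (range [0, 1]). Edges are processed
in increasing weight with the Felzenszwalb scale test: clusters A and B
merge when

```
w(A, B) <= min( Int(A) + lambda_mv/|A| , Int(B) + lambda_mv/|B| )
```

where `Int` is the largest dissimilarity already absorbed and |A| counts
supervoxels. Larger `lambda_mv` therefore produces fewer, larger
megavoxels at the cost of boundary adherence, and merges only happen along
RAG edges, so every megavoxel is a connected union of whole supervoxels.

The optional `gamma` applies an exponential similarity kernel before
merging: `w' = 1 - exp(-w * gamma / median(w))`, with `gamma = "auto"`
using the median edge weight. Small gamma compresses all dissimilarities
toward zero — neighbors look more alike — and so yields fewer megavoxels;
`gamma = NULL` disables the kernel. The exact agglomeration objective was
an open design point; this form was chosen because it is deterministic
(edges sorted by weight with id tie-breaks) and reproduces the documented
qualitative behavior of both lambda and gamma.

## Annotation and morphology

Annotation levels hold one integer label per voxel (−1 = unlabeled), with
optional parent–child links between labels of successive levels; child
annotations are confined to their parent's voxels, and the containment
violations of a stroke are counted and reported. Strokes label the pen
footprint directly (voxel mode) or every super-region the footprint
touches (supervoxel/megavoxel mode). The pen footprint is an **in-plane
disk** of the given radius — annotation is a slice-wise gesture, and a
2D footprint keeps a stroke's reach predictable; whether the original
interactive tool used a 3D ball is not documented, so the disk is the
package's choice, noted here. Within a level the last stroke wins;
commitment and refinement never overwrite *other* labels.

Morphological refinement (dilation, erosion, opening, closing, fill
holes) uses the discrete Euclidean ball of radius 1–20, implemented
through the exact squared Euclidean distance transform, so large radii
cost the same as small ones. Scopes: a single slice, all slices in 2D
(the recommended default), or the full 3D volume. Dilation only claims
unlabeled voxels and respects parent containment.

## Model training

Per-region descriptors are five order statistics (mean, sd, 25/50/75th
percentiles) of each selected source channel — low-dimensional, robust and
classifier-agnostic; with k channels the design matrix has 5k columns.
Three classifier families sit behind one interface: random forests
(default, 100 trees), SVM with probability outputs, and a penalized
multinomial logistic model (the "online linear" family; its
hyperparameters are library defaults, fixed ridge penalty 0.01).
Training regions — supervoxels containing scribbled voxels, majority label
— always keep their user label in the output probabilities. All fitting is
seeded, so results are bit-reproducible.

Prediction refinement is MAP relabeling on the supervoxel RAG with unary
cost `-log p` and pairwise cost `refine_lambda * w_e` on disagreeing
neighbors: `w_e = 1` for Potts, and for the appearance mode
`w_e = exp(-(dmu)^2 / (2 s^2))` with `dmu` the difference of neighbor mean
intensities and `s` its median over edges, so similar-looking neighbors
are coupled harder. The solver is iterated conditional modes with a fixed
sweep order — simpler than graph cuts and adequate at supervoxel-graph
scale; each sweep's energy is recorded and asserted non-increasing in the
tests. At `refine_lambda = 0` refinement reduces to the unrefined argmax.

The confidence slider maps to the **top-two probability margin**:
a region is committed iff `(p1 - p2) * 100 >= confidence`. This
reproduces both documented endpoints — confidence 0 assigns every
unlabeled region to its closest match; confidence 100 assigns only
regions where a single class holds all probability mass — and is monotone
in between. `iterate_training()` loops train → refine → commit until no
region is unlabeled, committing the remainder at confidence 0 when a
round stops making progress.

## Label splitting

`extract_objects()` decomposes chosen labels into connected components
(26-connectivity by default, so diagonally touching organelles stay one
object; configurable) and measures each object: mean/sd/variance of a
query channel, voxel and calibrated volume (voxel size triple from the
caller, default 1), centroid, bounding box and per-axis extents. Rules
(`<, <=, >, >=, between`) conjoin within a rule label; across labels the
first match wins, and an optional "others" label collects the unmatched.
Splits are saved into an empty annotation level; long-format statistics
export as CSV with 17 significant digits, so re-imported values are
bit-identical, and pairwise measure plots are emitted per measure pair.

## Synthetic phantoms

Two generators provide ground truth for every test:

* `make_multiregion()` — nested ellipsoids (or parallel slabs) with unit
  intensity steps and Gaussian noise; defaults (64³, 4 regions, contrast
  1, noise sd 0.1) emulate a high-contrast microCT-like volume with an
  SNR of 10. The slab layout at `n_regions = 2` is the two-phase step
  phantom used for boundary-recall checks.
* `make_organelle_cell()` — ellipsoidal blobs of varied size/intensity
  (radii 3 to size/10 voxels, intensities 0.8–1.2) and thin tubes (radius
  1–2 voxels) over a linear background gradient, placed by rejection
  sampling with a 2-voxel gap so each object is a separate truth
  component; noise sd is set from the requested SNR (foreground contrast
  / noise sd; default 3, a plausibly low cryoET-like value, with SNR 5
  used for the cryoSXT-like configuration).

Both are fully deterministic under their seed and record every generative
parameter. They emulate the *intensity statistics* of the three regimes,
not the physics: there is no projection/reconstruction simulation, no
contrast transfer function, and missing-wedge elongation is only coarsely
available as an optional axial blur. Passing tests therefore demonstrate
the pipeline's correctness and its behavior under noise and low contrast,
not performance on reconstruction artifacts specific to real tomograms.

## Bundled configurations and problem sizes

Three executable configs under `inst/configs/` mirror the documented
parameter sets for the three regimes, applied to matching phantoms:
`microct.yaml` (model-training loop on the multiregion phantom),
`cryoet.yaml` (layered filter set plus the super-region hierarchy on the
low-SNR organelle phantom) and `cryosxt.yaml` (super-region annotation,
morphology and label splitting, no model training). Because the phantoms
are 64³ rather than full-size tomograms, scale-dependent parameters were
re-matched once to the phantom scale and then frozen: TV lambda 0.5–1
(unit contrast), supervoxel shape 5×5×5 with compactness 20–50 (organelle
radii of 3–10 voxels), refinement lambda 50. Unit tests use 6³–32³ grids
for oracle comparisons and 48³–64³ volumes for end-to-end checks; these
sizes keep the whole suite and the acceptance script comfortably
reproducible on a single CPU.

The ROI and all coordinates are **1-based closed intervals** in `(z, y,
x)` order — the native R array convention; keeping the public interface on
R's indexing avoids a permanent off-by-one translation layer inside the
package.

## Known limitations

* The megavoxel objective is a documented stand-in honoring the stated
  parameter semantics, not a reimplementation of any specific published
  agglomeration objective.
* ICM finds a local MAP optimum; with very large `refine_lambda` it can
  over-smooth thin structures (tubes) — the documented mitigation is
  smaller supervoxels and moderate lambda.
* TIFF exports store 32-bit floats rescaled to [0, 1] with the original
  range in a JSON sidecar (the installed TIFF binding does not persist
  out-of-range floats); HDF5 round-trips are exact, MRC exact to the
  declared on-disk mode.
* No GPU paths, no transfer of trained models across volumes, no GUI.
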