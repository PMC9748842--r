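---
title: "Homologous-point registration of histology and MR images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homologous-point registration of histology and MR images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The registration problem

Transferring pathologist annotations from whole-mount histology slides onto
the corresponding T2-weighted MR slices requires a deformable registration
between two modalities with radically different appearance. `hpreg`
implements a homologous-point pipeline for this task with three stages:

1. **Landmark generation** — a difference-of-Gaussians (DoG) scale-space
   detector selects high-information points on the moving (histology) image:
   candidates below a contrast threshold of 0.04 (on `[0, 1]`-scaled
   intensities) are discarded, the remaining points are scored by the
   Hessian trace-squared-over-determinant edge surrogate, the top 19% by
   edge score are classified as *edge* points and the rest as *interior*
   points, and a minimum pairwise distance is enforced by greedy sequential
   elimination in which edge points take priority (the interior point always
   loses an edge–interior conflict).
2. **Homologous point prediction** — a three-headed network embeds both
   images into `N x d` patch-token matrices (a small patch CNN plus learned
   position embeddings), encodes each branch with a stack of
   locality-preserving transformer blocks (multi-head self-attention
   followed by a convolutional feed-forward: 1x1 expansion to `4d`, 3x3
   depthwise convolution on the `sqrt(N) x sqrt(N)` token grid, 1x1
   projection), gathers the moving-branch token under each landmark, forms
   the row-stochastic softmax similarity against all fixed-branch tokens,
   and reads out each landmark's fixed-space position as the similarity-
   weighted average of patch centers (a soft-argmax over the meshgrid
   spanning `[p/2, S - p/2]` with spacing `p`) plus the landmark's offset
   from its own patch center. Padding rows — the `(0, 0)` sentinels — are
   masked back to `(0, 0)` at the output.
3. **Transform resolution** — a thin-plate spline (kernel `U(r) = r^2 log
   r`) is fitted from the landmark/prediction pairs and the moving image is
   backward-warped into fixed-image space with bilinear sampling.

Evaluation uses average control point deviation (mean Euclidean distance
between held-out ground-truth pairs after mapping the moving-side points
through the solved transform) and the Dice coefficient of the organ masks.
The ground-truth pairs score the transform; they never enter the fit.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `contrast_threshold` | 0.04 | DoG contrast cutoff on `[0,1]` intensities |
| `edge_fraction` | 0.19 | fraction of candidates classified as edge points |
| `min_dist` | 30 px | minimum landmark spacing at 512 x 512 |
| `pad` | 50 px | frame margin after foreground center-zoom |
| `image_size`, `patch_size` | 512, 16 | network frame and patch side |
| `embed_dim`, `n_blocks` | 128, 6 | token width and encoder depth per branch |
| `L` | 75 | fixed landmark-list capacity |
| `tps_max_dev` | 16 px | augmentation control-point displacement cap |
| `rotation_range` | 20 deg | fixed-side rotation augmentation range |
| `epochs` | 128 | full-scale training schedule |
| `tps_lambda` | 1 | TPS regularization when fitting *predicted* pairs |

`min_dist` at the default produces point sets of a few dozen landmarks at
512 x 512, comfortably inside the `L = 75` capacity. The patch size is a
genuine free parameter of the architecture: it is not fixed by the published
description, so it stays a configuration knob (`parameter_count()` lets a
user search configurations against a known parameter budget; our
reconstruction does not uniquely pin down the patch size or head count, so
no exact architecture replication is claimed).

## Design choices on genuinely open points

* **Coordinate convention.** Points are `(y, x)`, 0-based, continuous, with
  pixel `i` spanning `[i, i+1)`; patch centers follow the continuous `p/2`
  convention the soft-argmax meshgrid dictates. All point-mapping operations
  are covered by round-trip tests.
* **Validity masks, not sentinels.** The `(0, 0)` padding sentinel is
  honored at the model boundary, but internally every point carries an
  explicit validity flag: after the 50-px center-zoom no legitimate landmark
  can sit at exactly `(0, 0)`, yet the mask keeps every code path
  well-defined even for raw, un-zoomed inputs.
* **Similarity softmax.** The similarity head uses raw dot products (no
  `1/sqrt(d)` scaling); a temperature knob exists for experimentation but
  defaults to 1. The *encoded* fixed-branch embeddings enter the similarity,
  and the two branches never share weights. Multi-head attention inside the
  encoder blocks does use the conventional `1/sqrt(d_head)` scaling,
  pre-norm placement and GELU activations.
* **Augmentation realization.** The random TPS augmentation displaces a
  4 x 4 control grid by i.i.d. per-axis uniform offsets capped at
  `tps_max_dev`. The displaced grid defines the *backward* (output-to-input)
  map, so the image warp is a single exact bilinear resampling; ground-truth
  points are carried forward by fixed-point inversion of the same map
  (converges below 1e-8 px for these near-identity deformations). This keeps
  image and labels consistent to well under half a pixel, which the
  delta-marker tests verify. Rotation augmentation applies to the fixed side
  only, also in mono-modal examples.
* **Branch switching.** Mono-modal examples (probability 0.5, drawn
  per-example as a seeded Bernoulli rather than a stratified half-split —
  same expectation, simpler bookkeeping) route both sides through the single
  modality's branch, so each branch only ever sees its own modality. A
  gradient-isolation test asserts that an all-histology mono-modal batch
  produces exactly zero gradient in the MR branch.
* **TPS regularization.** `fit_tps()` defaults to exact interpolation
  (`lambda = 0`), which is the right contract for clean point sets and for
  ground-truth transforms. When the *pipeline* fits network-predicted
  correspondences — which carry per-point noise — `run_register()` and
  `evaluate_pipeline()` default to a mild `lambda = 1` (pixel units) so a
  single noisy correspondence cannot fold the warp; the value is exposed
  everywhere.
* **Optimizer.** Adam (`lr` 1e-4 at full scale, batch 4). The scaled-down
  study below uses `lr` 2e-3: a model two orders of magnitude smaller
  tolerates — and needs — a proportionally larger step size on its short
  schedule.

## The phantom generator

Real whole-mount slides and their MR partners cannot ship with a package,
so every stage is exercised against synthetic phantoms with *known*
correspondences. A phantom is an organ-scale smooth blob (a low-order
Fourier perturbation of an ellipse) containing 2–5 internal structures and
a urethra-like hole. The moving image renders this geometry in a
histology style: bright field, fine-grain texture, dark contour lines whose
stain density varies along the boundary, and gland-like dark blobs sitting
on the stain maxima — the blob-scale features a DoG detector keys on in
stained tissue. The fixed image renders the *deformed* geometry under a
distinct intensity mapping with coarse noise and mild blur, so cross-modal
pairs differ in both appearance and geometry. The deformation is a random
thin-plate spline on a 4 x 4 grid whose control offsets are rescaled in
closed form so the mean ground-truth displacement equals the requested
magnitude exactly (TPS displacements are linear in the control offsets).
Ground-truth pairs sample the organ boundary (half) and internal contours
(half), exactly the placement logic used for manual control points.

What the phantoms do **not** emulate: real stain variability, scanner
artifacts, partial-volume effects, and the appearance statistics of
prostate tissue. Passing the phantom study shows the pipeline's machinery —
detection, correspondence, resolution, evaluation — is correct and can be
learned end-to-end; it does not certify clinical accuracy. The
`degrade_phantom()` modes (tear, fold, partial section) exist as a
stress-test harness for the artifact robustness question, which remains
future work.

## The scaled-down end-to-end study

`scripts/acceptance.R` (and the heaviest test) trains the tiny
configuration — 128 x 128 frames, `p = 8`, `d = 32`, 2 blocks, `L = 32` —
on 200 phantoms with 12-px mean deformation, mono- plus cross-modal
examples, for 28 epochs with Adam at a peak `lr` of 2e-3 cosine-decayed to
10% (batch 4), keeping the best-validation-loss weights; it then runs the
*full* pipeline (landmark selection at `min_dist` 9, prediction, TPS fit at
`lambda = 5`) on 20 held-out phantoms. Reported quantities: mean control
point deviation of the registered phantoms versus the identity baseline
(the phantoms' 12-px mean displacement), the percentage reduction, and
organ-mask Dice before and after registration. Problem sizes were chosen so
the whole study runs in minutes on one CPU; the full-scale configuration
trains the same code path, only larger.

What to expect from the scaled-down model is worth stating plainly. At
roughly 1.5% of the full architecture's parameters and a few thousand
optimizer steps, the network learns within-modality template matching to a
couple of pixels and global cross-modal alignment well — registered-mask
Dice improves on essentially every held-out phantom — but its *per-point*
cross-modal precision saturates around ten pixels, so the control point
deviation improves only modestly over the identity baseline. Diagnostic
probes (mono-modal self-matching error of ~2 px versus ~10 px cross-modal,
flat error-versus-confidence profiles, and insensitivity to landmark
density, TPS regularization and similarity temperature) localize the gap to
the cross-modal representation itself rather than to the detector, the
resolver or the readout. Closing it is a matter of capacity and training
budget — exactly the two things the scaled-down study deliberately caps.

## Numerical notes and limitations

* The DoG pyramid uses 3 scales per octave, `sigma0 = 1.6`, octaves until
  the short side drops below 16, no initial upsampling; blurring is
  banded-matrix convolution with replicate boundaries, so no wraparound
  extrema appear at the frame. Sub-pixel refinement (3-D quadratic fit) is
  on by default and contrast is measured at the refined position; a flag
  falls back to the raw DoG value.
* Ties in edge classification break by higher contrast, then scan order;
  the greedy elimination order (edges by descending contrast, then
  interiors) makes the whole detector deterministic — two runs on the same
  image are identical.
* `fit_tps()` refuses collinear or duplicate sources at `lambda = 0`,
  naming the offending points; bending energy is exposed and tested to be
  zero exactly on affine target sets and non-increasing in `lambda`.
* Degenerate inputs: constant images normalize to all-zeros and produce no
  candidates; an empty foreground raises an explicit error; a zero-valid
  loss mask is defined as loss 0 with a warning.
* The forward pass is deterministic given weights; training is reproducible
  under a fixed seed up to floating-point reassociation in BLAS.
* Known limitations: no 3-D volume support, no descriptor matching (the
  detector only), only the TPS transform family ships, and training at the
  full 512/128-d scale is CPU-days in this pure-R implementation — the
  package's value at full scale is inference and evaluation; the scaled
  study demonstrates learnability.
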