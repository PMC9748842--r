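# hpreg — homologous-point registration of histology and MR images

`hpreg` registers 2-D whole-mount histology slides (moving image) onto their
corresponding T2-weighted MR slices (fixed image) by predicting *homologous
points* — pairs of coordinates marking the same anatomical location in both
modalities — instead of predicting transform parameters directly. It is
aimed at radiology–pathology correlation work, where pathologist annotations
must be carried from stained tissue into MR space, and at anyone who needs a
transform-agnostic, mask-free deformable registration between modalities
with very different appearance.

## The method

The pipeline has three stages:

1. **Landmark generation.** A difference-of-Gaussians (DoG) scale-space
   detector proposes candidate points on the histology image. Candidates
   with contrast `|D| < 0.04` (intensities in `[0, 1]`) are dropped; the
   rest are scored with the Hessian edge surrogate `Tr(H)^2 / Det(H)` and
   the top 19% by edge score are classified as *edge* points, the others as
   *interior* points. A minimum pairwise distance is enforced by greedy
   sequential elimination in which edge points take priority over interior
   points.
2. **Homologous point prediction.** A three-headed network takes the
   histology image `M`, the MR image `F`, and the landmark list
   `X ∈ R^{L×2}` (padded with `(0,0)` to `L = 75`). Each image is sliced
   into `p × p` patches, embedded by a small CNN plus learned position
   embeddings into `P_m, P_f ∈ R^{N×d}` (`N = (512/p)^2`, `d = 128`), and
   encoded by six locality-preserving transformer blocks per branch
   (multi-head attention + 1×1 / depthwise-3×3 / 1×1 convolutional
   feed-forward); the two branches share no weights. The encoded moving
   tokens under the landmarks, `P'_m`, are compared against all encoded
   fixed tokens by row-wise softmax dot products, `S = softmax(P'_m P̂_f^T)`,
   and each landmark's fixed-space position is read out as the
   `S`-weighted average of the patch-center meshgrid (a soft-argmax) plus
   the landmark's offset `O = (X mod p) − ⌊p/2⌋` from its own patch
   center. Padding rows are masked back to `(0, 0)`.
3. **Transform resolution.** A thin-plate spline (`U(r) = r² log r`) is
   fitted on the predicted pairs and the histology image is backward-warped
   into MR space. Any point-cloud-resolvable transform could be substituted;
   TPS is what ships.

Training minimizes the masked mean absolute error between predicted and
annotated points, with random TPS augmentations (control-point displacement
≤ 16 px) on both sides, rotations in `[−20°, 20°]` on the fixed side, and a
50% *mono-modal* schema: half the examples present two differently-augmented
copies of a single modality, with the patch-encoder branches switched so
each branch only ever sees its own modality.

Evaluation uses **average control point deviation** (mean Euclidean distance
between held-out ground-truth pairs after applying the solved transform) and
the **Dice coefficient** of organ masks.

## Worked example

No clinical data ships with the package; the phantom generator produces
modality-styled image pairs with known ground truth:

```r
library(hpreg)

ph <- generate_phantom(seed = 7, size = 128, deformation_px = 12,
                       n_gt_points = 20)
ph
#> <hp_phantom: 128x128, 20 GT pairs, mean displacement 12.00 px, seed 7>

lm <- select_landmarks(ph$moving, min_dist = 9, max_points = 32)
lm
#> <hp_points: 12 points (12 valid, 3 edge)>

# how far apart the modalities start, and what a perfect solve would score
control_point_deviation(identity_tps(), ph$gt_moving, ph$gt_fixed)
#> [1] 12
control_point_deviation(ph$true_deformation, ph$gt_moving, ph$gt_fixed)
#> [1] 0

dice(ph$moving_mask, ph$fixed_mask)          # organ overlap before warping
#> [1] 0.6701909
oracle <- warp_image(ph$moving_mask, ph$gt_moving, ph$gt_fixed)
dice(oracle$pixels > 0.5, ph$fixed_mask)     # after the oracle TPS warp
#> [1] 0.9307702
```

`control_point_deviation()` is the mean distance, in pixels, between the
ground-truth fixed-space points and the moving-space points mapped through a
transform — the identity scores the phantom's mean deformation (12 px), a
perfect solve scores 0. The same phantom run through the *learned* pipeline
(landmarks, `predict_points()`, `fit_tps()`) is what
`phantom_registration_study()` measures after training the small
configuration; see below.

Command-line entry points (`inst/cli/hpreg`) wrap the same functions:
`select-landmarks`, `register`, `train`, `evaluate`, `synth`.

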