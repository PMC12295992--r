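---
title: "One-stage multitask vessel segmentation and centerline extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-stage multitask vessel segmentation and centerline extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(centrex)
```

## The problem

Vascular modeling needs two coupled products from a CTA volume: a voxel
segmentation of the vessel lumen and its centerline — the medial curve —
as an ordered polyline with real-valued coordinates. Classical pipelines
derive the centerline from the mask (thinning, Voronoi/minimal-cost
paths, per-slice centroids) and then repair the result: pruning spurious
branches, reconnecting fragments, smoothing. Every repair step adds
error and a failure mode. `centrex` implements a one-stage alternative:
a single hybrid network predicts both the mask and a connected polyline
of `num_points` points in one forward pass. Chain connectivity is a
structural property of the output — point `i` is connected to point
`i+1` by construction — so no post-processing exists to fail.

## The model

Three modules share one five-stage backbone:

* **Encoder** — five stages of stride-2 convolution followed by a
  mobile inverted bottleneck block (pointwise expansion, depthwise
  3×3×3 convolution, squeeze-excitation, pointwise projection, residual
  connection; SiLU activations). Stage $s$ is downsampled by $2^s$ with
  ceiling division, so any input with all axes ≥ 32 is valid.
* **Voxel decoder** — U-Net style: trilinear upsampling to the next
  skip resolution, concatenation with the encoder skip, then two
  (convolution → instance norm → ReLU) blocks per stage. A 1×1×1
  convolution emits logits at half resolution; these are trilinearly
  upsampled and refined by a small full-resolution convolution over
  [upsampled logit, input volume], whose final layer is
  zero-initialized so refinement starts as pure upsampling. A sigmoid
  yields per-voxel lumen probabilities on the input grid.
* **Centerline decoder** — starts from a randomly initialized polyline
  in the normalized $[0,1]^3$ frame and refines it over five stages,
  sampling from the voxel-decoder feature pyramid coarse-to-fine. Each
  stage: trilinearly sample point features at the current coordinates;
  predict `neighbors_k` neighbour coordinates per point (tanh-bounded
  offsets of at most one stage voxel); sample neighbour features; fuse
  [point features, neighbour features, candidate coordinates] with a
  pointwise linear map; refine with residual graph-convolution blocks
  (graph convolution over the chain adjacency with symmetric
  normalization → SiLU → LayerNorm, twice per block); and emit
  per-point coordinate offsets from a single zero-initialized graph
  convolution. Offsets are added to the incoming coordinates and
  clamped to $[0,1]^3$.

Normalization inside the network is instance-style (per-channel over
space) rather than batch statistics, so batch-1 CPU training and
inference behave identically. At a 1×1×1 bottleneck the spatial
statistics are degenerate and only the affine part of the norm is
applied.

Design choices where the architecture was genuinely open, and why:

* *Sampling source.* Point features are sampled from the voxel-decoder
  stage maps (not the encoder): those maps are directly supervised to
  encode lumen membership, which is exactly the evidence the point
  refinement needs.
* *Graph convolution variant.* Degree-normalized aggregation over self
  + chain neighbours ($\hat A = D^{-1/2}(A+I)D^{-1/2}$). It is the
  simplest operator that matches "graph convolution over the polyline";
  alternatives can be plugged in at one site.
* *Offsets, not absolute coordinates.* Every refinement stage predicts
  residual offsets with a zero-initialized head, so the decoder starts
  as the identity on the polyline and training shapes corrections;
  this makes early training stable and testable. A fully-residual
  decoder must *learn* to contract an arbitrary random initialization
  onto the vessel; a `stage1_absolute = TRUE` option makes the first
  stage predict absolute coordinates instead (which removes the
  initialization from the output path structurally but, in our
  experiments at CPU scale, traded peak accuracy for that insurance
  and is therefore not the default).
* *Coordinates as features.* The fusion layer sees the candidate
  coordinates along with sampled features. The coarse stage maps
  (2–6 voxels per axis) cannot encode "where am I" precisely enough
  for a position-dependent correction; feeding the coordinate in makes
  the mapping from an arbitrary random initialization to the vessel
  learnable at small scale.
* *Neighbour count and bound.* `neighbors_k = 4` with tanh-bounded
  offsets of one stage voxel keeps neighbourhood sampling local and the
  sampler differentiable everywhere.

## The loss

The training loss combines four terms (all centerline terms operate in
the normalized coordinate frame; metrics are computed in mm):

* **Voxel loss** `voxelLoss()`: focal + dice,
  $-\sum_i M^t_i (1-M^p_i)\log M^p_i - 2\sum_i M^t_i M^p_i / \sum_i (M^t_i + M^p_i)$,
  natural log, probabilities clamped at $10^{-7}$. At a perfect binary
  prediction the loss tends to $-1$. How the class sum of this loss
  should read for a single-channel sigmoid output is ambiguous. The
  exported default scores the vessel class only; training enables
  `include_background`, which adds the complementary class
  ($M^t_{bg} = 1 - M^t$, $M^p_{bg} = 1 - M^p$; dice averaged over the
  two classes, same $-1$ perfect limit). The distinction matters: with
  the vessel-only form, background confidence is never directly
  penalized, and once background logits saturate the dice term's
  restoring gradient is far too weak to recover — we observed masks
  collapsing toward all-foreground exactly this way. The mask head
  additionally starts from a negative logit bias so the foreground
  grows outward from true lumen voxels.
* **Chamfer distance** `chamferLoss()`: symmetric nearest-neighbour
  sum with unsquared Euclidean norms by default (a `squared` flag is
  provided). Applied to every decoder stage's polyline (deep
  supervision, a flag disables it).
* **Edge-length regularizer** `edgeLengthReg()`: sum of squared
  consecutive-edge lengths; for fixed endpoints it is minimized by
  uniform spacing. A `variance` mode is provided as the alternative
  reading of "uniform edge length".
* **Point-in-lumen penalty** `pointLumenReg()`: the focal+dice form
  evaluated on mask probabilities sampled trilinearly at the predicted
  points against an all-ones target, jointly over the point set (a
  per-point dice would be degenerate). The sampled probabilities are
  stop-gradient: the penalty moves points into the lumen but never
  inflates the mask to please the points.
* **EMA normalization** `emaInit()/emaUpdate()`: voxel and lumen terms
  enter the total as $\bar L = \alpha\bar L + (1-\alpha)L$ with
  $\alpha = 0.9$; only the current loss carries gradient, weighted
  $1-\alpha$. The literal EMA expression is used as the training term;
  a `normalize_by_ema` mode (raw loss divided by the detached running
  value) is available as the alternative reading.

## Training and defaults

AdamW (decoupled weight decay $10^{-4}$, a stability choice; the
optimizer and learning rate $10^{-3}$ are standard for this
architecture family), global gradient-norm clipping at 1.0, a cosine
learning-rate decay to 5% over the run (short schedules otherwise stay
noisy to the end), and Polyak averaging of the weights over the
trailing 20% of iterations. The full-scale schedule is 80 epochs ×
1000 iterations with 96 centerline points; the package's canonical CPU
configuration — used by the test suite and by `scripts/acceptance.R` —
is the tiny preset: 48³ volumes at 2 mm spacing, encoder channels
(8, 16, 24, 32, 48), 32 points, 500 iterations on 64 phantoms. Those
problem sizes were chosen so a complete train-and-evaluate cycle is an
interactive experiment on one CPU core, while remaining large enough
that the centerline decoder must genuinely localize a randomly placed,
randomly oriented tube.

Every polyline initialization during training is freshly random (a
straight segment between two uniform points in $[0.2,0.8]^3$), so the
decoder learns a map from any initialization to the vessel rather than
memorizing one starting shape. Learning that contraction fully is the
hard part of the short schedule: the mask head converges within a few
hundred iterations, while the centerline head's held-out accuracy
still varies noticeably across training streams and inference
initializations (see Known limitations).

## Synthetic phantoms: what they emulate, and what not

`phantomSpec()` / `makePhantomDataset()` generate unbranched aorta-like
tubes: a candy-cane curve (two straight limbs joined by an arc),
constant or linearly tapering radius, rasterized on a 2 mm isotropic
grid, rendered at 300 HU lumen over 0 HU background with a 1 mm
partial-volume blur, and annotated with ground-truth points at 6 mm
arclength spacing (≈ 20–45 points per case at default scale — the
sparse manual-annotation density regime of aortic CTA). Default curve
scales (arc radius 40–80 mm, tube radius 8–15 mm) mimic aortic
geometry; `phantomDistributionTiny()` scales the curves to a 48³ grid.

Phantoms have exact analytic ground truth, which is what makes the
oracle tests possible. They do **not** emulate: bifurcations, wall
thrombus or calcifications, contrast inhomogeneity, neighbouring
bright organs, or anisotropic acquisition. Passing the end-to-end
recovery tests therefore shows the method's machinery (losses,
decoders, metrics, training loop) works as specified — it does not
certify clinical performance on patient CTA, which requires the
full-scale data and schedule.

## Metrics: canonical definitions

Published explicit definitions of the 1D metric adaptations were not
available, so the package fixes one canonical set (documented here so
numbers are comparable across runs of this package):

* both polylines are resampled at 0.5 mm arclength steps
  (endpoint-anchored, $n = \lceil L/\text{step}\rceil$ equal
  intervals; nesting under step halving holds exactly when $L$/step is
  integral);
* distances are point-to-**polyline** (point-to-segment over the
  chain), not point-to-point — with 6 mm ground-truth spacing a
  point-set distance would inflate errors by up to 3 mm;
* Surface Dice at tolerance $\tau$ counts resampled points from both
  directions within $\tau$ of the opposite polyline;
* HD95 is the linearly interpolated 95th percentile of the pooled
  directed distances, ASSD their mean;
* volumetric Dice thresholds probabilities at 0.5 and scores two empty
  masks as 100;
* across cases, metrics aggregate as mean ± population standard
  deviation.

The mass-centroid baseline (`massCentroidBaseline()`) computes
per-axial-slice foreground centroids; slices whose foreground is
disconnected are flagged — on arched tubes a slice cuts the vessel
twice and the centroid lands between the limbs, which is precisely the
failure mode that motivates learning-based extraction.

## Perturbations

Artifact models: additive Gaussian noise (variance 15 HU², read as
HU² since a variance in HU would be dimensionally inconsistent;
configurable), a global calibration shift uniform in ±10 HU, and
linear motion blur with amplitude 1–3 voxels. The blur kernel is a
normalized uniform line of length amplitude+1 voxels; even lengths are
symmetrized (the mean of the two integer centerings) so that
mirror-padded convolution conserves total intensity exactly.

Geometric robustness transforms: similarity transforms (scale 0.9–1.1,
rotations ≤ 10°) and control-grid distortion (4³ grid, border points
fixed, displacements ≤ 4 mm — magnitudes chosen small relative to the
tube radius, and checked: the forward map's Jacobian determinant must
stay positive or the draw is rejected). Images are resampled with
Catmull-Rom cubic interpolation; masks are Gaussian-smoothed (σ = 1
voxel), trilinearly resampled and re-thresholded at 0.5; ground-truth
points are mapped with the exact analytic transform (rigid) or by
adding the displacement field evaluated at the points (distortion,
with the image pulled back through the small-displacement inverse
approximation $T^{-1}(y) \approx y - u(y)$). Identity parameters
short-circuit to the untouched inputs.

## Numerical choices and degenerate inputs

* Chamfer/metric square roots are guarded with $10^{-12}$; log terms
  clamp probabilities at $10^{-7}$.
* Grid-sample coordinates outside $[0,1]$ clamp to the border, where
  the coordinate gradient is zero.
* Resampling a polyline shorter than one step returns its endpoints.
* A rasterization radius below the voxel scale yields an empty mask
  with a warning; `phantomSpec()` itself requires radius ≥ 2 × max
  spacing.
* Ties in nearest-neighbour assignments break toward the first index;
  HD95 uses the default linear-interpolation percentile.
* Training aborts with a diagnostic checkpoint on a non-finite loss.

## Known limitations

At the CPU scale the end-to-end recovery of the centerline is
stochastic in a way the full-scale schedule is not: across independent
training streams of the identical canonical configuration, held-out
SD-3 at the default inference initialization ranged from the
mid-sixties to the mid-nineties percent, and a given trained model's
accuracy also varies across inference initializations (the residual
decoder must learn to contract an arbitrary start, and 500 iterations
do not always get it there). The mask head does not share this
fragility (held-out volumetric Dice is consistently ≈ 98%). Variants
that remove the initialization from the output path structurally
(`stage1_absolute`) or widen the training initialization distribution
traded away peak accuracy in our experiments and are therefore
options, not defaults. Other limitations:

* Topology is fixed to a single chain: bifurcating trees are out of
  scope by design; the chain adjacency would need to be replaced by a
  learned or dynamic graph.
* The voxel decoder computes logits at half resolution plus a light
  full-resolution refinement; extremely thin vessels (radius near one
  voxel) would need a full-resolution decoder stage.
* The displacement-field inverse is first-order; at displacements much
  larger than the defaults the image/point consistency degrades.
* CPU-scale training runs minutes, not hours; the full-scale preset is
  provided but is not exercised by the test suite.
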