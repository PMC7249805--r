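---
title: "Vessel centerline delineation in OCT-A: models, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel centerline delineation in OCT-A: models, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octaseg)
```

## The problem

OCT angiography derives a 3D blood-motion map from decorrelation between
successive OCT scans. The retinal slab — a stack of geometrically
flattened slices between the vitreo-retinal interface and the choroid —
is reduced to a 2D image by a maximum intensity projection (MIP), and it
is on this projection that vessels are delineated. Three properties of
OCT-A MIPs shape the whole design:

* vessel cross-sectional contrast fades away from the vessel middle, and
  vessels are rarely more than a few pixels wide, so 1-px **centerlines**
  are the annotation unit rather than full-width masks;
* microvasculature fills most of the space between larger vessels as an
  unresolvable bright texture, which must not be segmented;
* acquisition produces horizontally oriented stripe artefacts.

Formally, each pixel gets a posterior probability of lying on a vessel;
a convolutional network `f(X; θ)` maps the image to a probability map at
the same resolution.

## Networks

The base module is a residual U-Net. The encoder applies `n_blocks`
residual blocks (default 3; 5 supported for depth ablations), the first
`n_blocks − 1` followed by 2× max pooling, with feature counts doubling
at each deeper block from `base_filters` (64 by default; tests and the
scaled-down experiment use 8). The decoder mirrors this with 2×2
transposed convolutions, concatenating the encoder features of matching
resolution before each decoder block; a final 1×1 convolution and
element-wise sigmoid produce the probability map. Each residual block is
two 3×3 convolutions with ReLU and an identity shortcut (1×1 projection
when the channel count changes) — the reference the architecture cites
gives no layer-level detail, so this standard form was chosen. Inputs
whose sides are not multiples of `2^(n_blocks−1)` are reflect-padded
internally and cropped back, so output resolution always equals input
resolution.

Two refinement schemes wrap the base module:

* the **stacked hourglass** (`shn`) cascades `k` modules with distinct
  weights, each consuming the image concatenated with the previous
  module's prediction;
* the **recurrent U-Net** (`iunet`) applies one module `T` times with
  shared weights, feeding its own prediction back.

Every step — including the first — consumes the same 2-channel input,
with an all-zero prediction channel at step 1. The uniform interface is a
deliberate design choice where the refinement literature is ambiguous
about the first step: it makes the parameter ratio between `shn(k)` and
`iunet` exactly `k`, and the recurrent weight sharing exact. The
recurrent model's parameter count is independent of `T`.

## Losses

Class imbalance is severe (centerline pixels are a few percent of the
image even after dilation), so the cross-entropy is balanced by class
frequency: with vessel set `Y+` and background `Y−`,
`β = |Y−|/|Y|` multiplies the vessel term and `1 − β` the background
term. One published description of this loss swaps the *names* of the two
sets relative to the formula; we follow the formula, with the rare vessel
class receiving the large weight — the reading consistent with the
class-balancing lineage the loss descends from. `β` is recomputed per
image. Probabilities are clamped to `[1e−7, 1 − 1e−7]`; an all-background
target makes the loss identically zero and is flagged as degenerate.

Topological errors — holes that break vessel continuity, spurious
fragments — are penalised by a perceptual loss: mean squared differences
between frozen feature maps of the prediction and of the supervision
mask, taken post-ReLU at `conv1_2`, `conv2_2` and `conv3_4` of a
VGG19-shaped extractor (channel widths 64/128/256 at scales 1, 1/2, 1/4)
and weighted by `μ = (1e−2, 1e−3, 1e−4)`. Two extractor kinds exist:
`vgg19-imagenet` expects the published pretrained weights (not bundled;
the constructor errors with advice if they are unavailable), and
`seeded-random`, the default, freezes He-initialised random filters from
a fixed seed. Random frozen features are a recognised basis for
perceptual distances, and they keep every result in this package
reproducible offline; inputs are passed raw in `[0,1]` (replicated to 3
channels) since no pretrained normalisation applies. The supervision mask
fed to the extractor is the same 1-px-dilated centerline used by the
cross-entropy, as a float image.

The combined loss is the plain sum `L_comb = L_bce + L_topo`; the
relative weighting is carried entirely by `μ`. Intermediate supervision
applies `L_comb` at every refinement step: summed unweighted across
hourglass modules, and weighted by `w_t = 2t/(T(T+1))` across recurrent
iterations — strictly increasing weights that sum to one, which both
stabilises training and pushes the recurrence toward coarse-to-fine
refinement. Gradients flow through the fed-back prediction channel, i.e.
the recurrence is trained by full backpropagation through the unrolled
computation, end-to-end in one stage for the configured `T`.

## Training protocol

Adam with batch size 2; initial learning rate `1e−4`; inverse-time decay
`lr = lr0 / (1 + 0.5 · epoch)` — the decay unit is the epoch, since a
per-step unit would anneal thousands of times faster than any plausible
reading of "rate 0.5". An epoch is one pass over the rotation-augmented
training set. Training runs up to 6000 steps, with early stopping once 10
consecutive epochs bring no improvement in validation Quality and at
least 1000 steps have elapsed; "no improvement" means not strictly
greater than the running best. Validation computes mean Quality at
τ = 2 after thresholding at 0.5 and skeletonizing. The best-validation
checkpoint is retained.

Augmentation has an offline and an online part. Offline, the training set
is quadrupled by 90°/180°/270° rotations — lossless pixel permutations
that also turn the naturally horizontal stripe artefacts into vertical
ones, teaching invariance to both. Online, before every step: isotropic
scaling by a factor from `[0.8, 1.3]` (resolution-preserving:
scale, then center-crop or pad), elastic deformation by a
Gaussian-smoothed random displacement field (the same field warps image
and mask, the mask with nearest-neighbour sampling so it stays binary),
a brightness shift of magnitude `[0, 0.2]` with random sign, a contrast
scale from `[0.75, 1.25]` about the image mean, and erasure of eight
random 4×4 image patches. Published descriptions leave the brightness
operator, the canvas handling under scaling, the augmentation order and
the elastic hyperparameters unspecified; the choices above (additive
brightness, fixed order as listed, `σ = 8` px smoothing with 2 px
amplitude) are this package's, and erasures deliberately leave the mask
untouched so the annotation still supervises occluded vessels.

Cross-validation uses stratified 4-fold splitting: within each stratum
(pathology class) the ids are shuffled and dealt round-robin; fold `f`
tests on its share, validates on the next fold's share, and trains on the
rest, so test sets partition the dataset and every stratum with at least
`k` members reaches all three sets.

## Evaluation

Predictions are thresholded at 0.5 (strict `>`, ties to background) and
thinned to 1-px skeletons by two-subiteration morphological thinning
(Zhang–Suen family), which preserves 8-connectivity — the property that
makes Quality sensitive to breaks in vessel continuity rather than to
width. Matching between skeletons uses strict Euclidean tolerance
(`< τ`): on the integer grid distinct points are at distance ≥ 1, so
τ = 1 introduces no tolerance at all, and τ = 2 admits at most direct
pixel neighbours — the default everywhere. Completeness, Correctness and
Quality are the tolerance-relaxed recall, precision and IoU.

Degenerate conventions (the literature is silent): two empty skeletons
score (1, 1, 1); an empty prediction against a nonempty ground truth —
or the reverse — scores (0, 0, 0), flagged. Note that
Quality ≤ Correctness always holds, but Quality can exceed Completeness
when several predicted points match a single ground-truth point; no
claim to the contrary survives arbitrary point sets.

The precision–recall break-even point is computed pixel-to-pixel between
the raw probability map (not the skeleton — following the metric's
pixel-wise definition) and the 1-px-dilated centerline, on a fixed grid
of 255 thresholds with linear interpolation at the crossing; a fixed grid
keeps the sweep deterministic across images.

## The phantom generator

No OCT-A dataset is bundled, so the package generates phantoms with the
statistical structure that motivates the method: trees of branching
vessels grown from border seeds by bounded-curvature unit-step random
walks (branching probability 0.02/step, widths 2–5 px tapering by 0.8
per generation, at most 5 generations and 64 branches); a Gaussian
cross-profile with `σ = width/4` whose peak (contrast 0.55–0.95) sits on
the centerline, reproducing the fading contrast that makes centerline
annotation the only practical choice; a smoothed random background
texture (amplitude 0.12) playing the role of unresolvable
microvasculature; multiplicative speckle (σ = 0.08); and additive
horizontal stripe bands (amplitude 0.08, insertion probability 0.5 per
candidate band). For 3D, each branch carries a smooth random depth
profile and is rendered as a tube into a 16-slice stack; with noise
disabled the MIP of the stack equals the 2D rendering exactly, by
construction (the tube copies the in-plane profile into every slice
within width/2 of the local depth, and that depth interval always
contains an integer slice).

These defaults were chosen once, as a realistic-but-learnable regime: the
vessel-to-background contrast is clearly above the texture amplitude, as
it is for the larger vessels that clinical annotation targets. What the
phantoms do **not** emulate: pathology-specific vessel morphology, the
foveal avascular zone, true OCT speckle physics, and projection/shadowing
artefacts between slices. Passing phantom tests therefore demonstrates
that the implementation learns and scores curvilinear delineation
correctly — not clinical-grade performance.

## Numerical and scale choices

* Convolutions run in single precision through BLAS (im2col + GEMM);
  training-path gradient checks therefore use relative tolerances of a
  few percent, while the analytic cross-entropy gradient (computed in
  double precision) is verified to 1e−4.
* Default phantom size is 256 px (416 px — the 8 mm field of view at
  ~19 µm/px — is available via configuration); the scaled-down
  experiments in the test-suite use 64 px with 8 base filters and `T = 2`
  so a full train/evaluate cycle takes about three minutes on one CPU.
* The scaled-down recovery experiment
  (`phantom_recovery_experiment()`) trains for 500 steps with
  `lr0 = 1e−3`: the schedule is 12× shorter than the full 6000-step
  protocol, so the initial rate is scaled up accordingly; online
  augmentation is disabled there (offline rotations are kept), which
  also allows the supervision mask's extractor features to be computed
  once per sample.
* Probability ties at the 0.5 threshold go to background; matching uses
  strict inequality; Bresenham rasterization guarantees every branch
  trace is one 8-connected pixel path, and the lumen mask always
  contains the rasterized centerline.
* Early divergence (non-finite loss) aborts training with a diagnostic
  rather than continuing silently.

## Limitations

The 3D segmentation is strictly per-slice 2D aggregation: the model is
unaware of 3D context and inherits the known failure mode of segmenting
shadowing artefacts below large vessels. The seeded-random extractor is a
stand-alone design choice, not a numerical replica of ImageNet features;
when the published VGG19 weights are available the `vgg19-imagenet` kind
uses them with their training-time input normalisation. Wilcoxon
significance testing across models is left to the standard `stats`
routines on the per-subject Quality values.
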