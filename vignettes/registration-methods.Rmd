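---
title: "Weakly supervised deformable registration with snake convolutions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised deformable registration with snake convolutions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snakereg)
```

## The registration problem

Deformable registration seeks, for a moving image $I_m$ and a fixed image
$I_f$ on the same voxel grid, a dense displacement field $\phi$ such that
the warped image $I_m \circ \phi$, defined by
$(I_m \circ \phi)(p) = I_m(p + u(p))$ with trilinear interpolation,
resembles $I_f$ while $\phi$ stays smooth:

$$\hat\phi = \arg\min_\phi \; \big(1 - \mathrm{NCC}(I_f, I_m\circ\phi)\big)
  + \lambda \, \mathrm{Reg}(\phi).$$

`snakereg` implements this in two cooperating stages:

1. **An amortized predictor** — a Swin-UNet-style encoder–decoder with 3D
   dynamic snake convolutions in its head (`stunet()`), mapping a
   (moving, fixed) pair to $\phi$ in a single forward pass.
2. **An instance optimizer** (`instance_optimize()`) — per-case Adam
   refinement of a field against the registration energy.  During
   training the refined field $\phi_{opt}$ of each predicted $\phi$
   serves as a pseudo-ground truth, and the network is updated on
   $$L = \tfrac1n \sum (\phi - \phi_{opt})^2 + \lambda\,\mathrm{Reg}(\phi),
   \qquad \lambda = 0.02,$$
   a weakly supervised loop: better predictions seed better refinements,
   which in turn supervise better predictions.

All geometry is voxel-indexed and 0-based; displacements are in voxel
units (not millimetres), component order $(\Delta d, \Delta h, \Delta w)$.
Out-of-bounds samples clamp to the border, which avoids injecting zeros
into correlation windows at volume edges.  NIfTI affine headers are
stored on I/O but never used for resampling.

## Similarity, smoothness, and their gradients

The similarity is the **local squared correlation coefficient**: with
window sums over an $n^3$ box ($n = 9$ by default, the common choice for
brain MRI; windows shrink at the border),

$$cc(p) = \frac{\mathrm{cross}^2(p)}
               {\mathrm{var}_f(p)\,\mathrm{var}_m(p) + \varepsilon},$$

averaged over the volume.  $\varepsilon = 10^{-5}$ guards locally flat
windows (which score 0); identical images with non-degenerate local
variance score 1 up to $\varepsilon/\mathrm{var}^2$.  The measure is
invariant to positive affine intensity rescaling of either image.  The
smoothness penalty is the mean squared forward difference of the three
displacement components along the three axes, normalized so that a unit
displacement slope scores exactly 1 and any uniform translation scores
exactly 0; means (rather than raw sums) make the losses
resolution-independent while $\lambda = 0.02$ keeps its published value.

Because no automatic differentiation framework is involved, the package
carries **analytic gradients** of every objective: the correlation
gradient is assembled from box-filtered window statistics, the warp
gradient chains the image term through the trilinear sampler's position
derivative (the sampled spatial gradient of the moving image), and every
network layer implements an explicit backward pass.  All of these are
finite-difference checked in the test suite.

An optional SSIM term (Gaussian window, sd 1.5 voxels, standard
stabilizers) can be added to the optimization energy via
`loss_config(ssim_weight = ...)`; its default weight is 0 because the
refinement stage is already driven by the correlation term, and the SSIM
hook is kept for intensity-structure-sensitive applications.

## The 3D dynamic snake convolution

A standard $3^3$ kernel is linearized along one grid axis into
`points_per_kernel` = 9 taps.  Walking outward from the center, each step
moves one voxel along the axis while the two lateral coordinates bend by
learned offsets accumulated as running sums, each per-step offset bounded
by `max_step` = 1 voxel through a saturating odd squashing
(`max_step * tanh`).  Fractional positions are read by trilinear
interpolation.  Three axis-variants (one snake per axis) are evaluated
and fused — averaged by default; concatenation with a pointwise
convolution is available.  With the default specification the deformed
kernel can reach anywhere inside a $9 \times 9 \times 9$ cube: the
along-axis extent is the tap count, and each lateral extent is
$2\lceil \text{max\_step} \cdot 4\rceil + 1$.

The 9-tap/unit-bound default is forced by consistency: only a 9-point
linearized kernel with a unit per-step bound yields a selectable
$9^3$ receptive field from a $3^3$ base kernel.  Offsets are predicted
from the operator's own input features by a $3^3$ convolution
(zero-initialized, so the operator starts as an axis-aligned separable
convolution); each axis-variant carries independent channel-mixing
weights.  A slow loop-based reference implementation
(`dsconv3d_reference()`) ships alongside the fast gather-and-sum path
and anchors the operator's correctness tests.

## Network assembly

`stunet()` builds, for a configured input shape (divisible by 4, 16 or
larger per axis):

* a **convolutional stem** on the stacked pair: a full-resolution block
  (16 channels by default) and a strided half-resolution block ($C/2$
  channels) whose outputs re-enter the decoder as skips.  The stem sees
  both images — localizing correspondence requires the fixed image — a
  deliberate choice where the architecture description mentions only the
  moving image;
* a **patch embedding** of non-overlapping 2-channel $4^3$ patches
  (128 values) projected to $C$ channels, then a 4-stage shifted-window
  transformer encoder with patch merging (channel doubling) between
  stages.  Window attention uses pre-norm blocks, two-layer GELU MLPs,
  learned relative position biases, and cyclic-shift masking in every
  second block; odd grids are zero-padded to window multiples with
  padding masked out of attention;
* a mirrored **decoder** of swin stages and patch expansions whose skip
  connections are *multi-fusion dense*: each decoder scale concatenates
  the upsampled feature, the same-scale encoder feature, and a
  VGG-style branch (conv–norm–ReLU ×2 + max-pool) that drags the next
  shallower encoder feature down one scale, fused by two convolution
  blocks;
* a **head** at full resolution: a standard Conv3D block, then a dynamic
  snake convolution block, each followed by concurrent spatial/channel
  squeeze-and-excitation gating (channel gate from a pooled descriptor
  through a bottleneck, spatial gate from a pointwise convolution, fused
  by elementwise maximum), consuming the stem skips;
* a final $3^3$ convolution with 3 output channels, **zero-initialized**
  so an untrained network predicts the identity transform — the standard
  stable starting point for registration networks.

Normalization is group normalization by default (exact and deterministic
at batch size one); per-channel "batch" statistics are available as an
option.  Default full-scale widths are $C = 48$, depths $(2,2,4,2)$,
heads $(4,4,8,8)$; these are declared defaults, not published values.
`network_config_desk()` is the CPU-scale preset used throughout the
examples and tests: $C = 8$, one block per stage, $2^3$ windows, 8 stem
and head channels, on volumes of 16–48 voxels per side.

## The optimization stage and weak supervision

`instance_optimize()` treats the field's voxel vectors as free parameters
and runs `iterations` = 10 Adam steps (learning rate 0.1, $\beta_2$ =
0.999) on the energy.  Two numerical details matter:

* **Convergence tolerance.** Adam's update is scale-free: at a true
  fixed point (an already-aligned pair) float-noise gradients of order
  $10^{-17}$ would otherwise be amplified into full-size steps.
  Iteration therefore stops once the largest gradient component falls
  below `gtol` ($10^{-9}$), so aligned pairs stay exactly put.
* **Pseudo-label gating.** A refined field is used as supervision only
  if it improved the energy (threshold configurable as a fraction of the
  initial energy, default 0); otherwise the predicted field itself is
  the target, and the loss degenerates to the smoothness term.  This is
  the progressive pseudo-label idea: low-confidence refinements never
  steer the network.

The refined field is detached: supervision gradients never flow through
the optimizer into the network.  With `oss = FALSE` the trainer instead
minimizes the unsupervised energy directly through the warp — the
ablation partner of the weakly supervised mode.

Training follows the published recipe where it is stated: Adam at
learning rate $10^{-4}$, batch size one, label-safe augmentation
(random axis permutations and flips, with displacement components
permuted and negated consistently — exact and label-safe, chosen because
the published "random rotations" leave the angle range unspecified),
per-epoch validation by mean Dice of nearest-warped labels, and
best-validation checkpoint retention.

## Synthetic study conditions

Real brain MRI (and its 300-epoch, $160\times192\times224$ training
regime) is out of desk scope, so the generator fabricates cases with
exact ground truth:

* **Phantoms** (`make_phantom()`): four strictly nested randomized
  ellipsoidal shells around a jittered center — a cartoon of
  cortex/white-matter/ventricle nesting — with distinct per-structure
  intensities on $[0.3, 1]$, Gaussian noise (sd 0.02) and mild smoothing
  (sd 0.5 voxels).  The noise gives every correlation window usable
  texture, as tissue does; the smoothing keeps edges from being
  knife-sharp.
* **Ground-truth fields** (`make_smooth_field()`): Gaussian-smoothed
  white noise (sd 4 voxels), rescaled to a 2-voxel maximum displacement
  and verified fold-free by an exhaustive Jacobian scan (amplitude is
  backed off and the field regenerated if folding ever occurs).
* **Cases** (`make_pair()`): the fixed image is the warped moving image,
  so `evaluate` on the truth returns Dice 1.0 and 0% folding by
  construction; labels are always warped in nearest mode (trilinear
  label warping is refused everywhere).  An atlas-to-subject flavour
  without ground truth can be emulated by pairing independent phantoms.

What passing these tests shows — and does not show: the synthetic
phantoms exercise every computational path (multi-scale attention,
snake offsets, refinement, evaluation) under exactly known deformations,
but they have none of real MRI's bias fields, modality contrast,
resolution anisotropy or anatomical variability, so scores here do not
transfer to clinical data.

## Desk-scale study sizes

The heavier checks in the test suite use sizes chosen to exercise the
full system on one CPU:

* translation recovery: one $32^3$ phantom, ground-truth uniform
  translation of 1.5 voxels, 200 refinement iterations, foreground mean
  displacement error below 0.25 voxels;
* energy monotonicity: 20 seeded $32^3$ cases, 10 refinement steps each;
* training study: 30 epochs over 20 synthetic $24^3$ cases with 4 held
  out (desk network preset, seed 1), requiring held-out mean Dice
  strictly above the identity baseline;
* weak-supervision ablation: 3 seeds, each 12 epochs over 10 cases with
  3 held out, comparing the *trained endpoints* (final-epoch validation
  Dice) of the weakly supervised and unsupervised variants.  Endpoints
  are compared rather than best checkpoints because both variants pass
  through the identity-like start whose Dice can dominate early
  validation; the published comparison is likewise between final
  models.  The 12-epoch budget is where the two learning curves have
  separated in this desk setting.

## Known limitations

* Pure-R training is CPU-bound; the desk preset trains in minutes but
  the full-scale configuration is not practical without batching and
  accelerator support.
* Displacements are predicted directly (no diffeomorphic integration);
  invertibility is only encouraged by the smoothness term and measured
  by the Jacobian scan.
* Double precision throughout (R has no native 32-bit float arrays).
* The instance optimizer shares the predictor's energy but not its
  parameters; refinement quality therefore depends on the predicted
  initialization, which is the point of the feedback loop but also means
  a poor predictor refines slowly.

## A worked example

```{r example, eval = FALSE}
library(snakereg)

case <- make_pair(phantom_spec(shape = c(24, 24, 24)), field_spec(),
                  seed = 7)
set.seed(7)
net <- stunet(network_config_desk(c(24, 24, 24)))

# untrained = identity transform
res <- predict(net, case$moving, case$fixed)
max(abs(res$field$vectors))  # 0

# refine the identity field on this pair
ref <- instance_optimize(case$moving, case$fixed, res$field,
                         opt_stage_config(iterations = 50))
attr(ref, "energy_init"); attr(ref, "energy_final")

# score it
evaluate_registration(list(ref), list(case))
```
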