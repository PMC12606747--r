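---
title: "Structure-aware multi-animal pose estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware multi-animal pose estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structpose)
```

## The problem

Behavioral imaging of small model organisms — *C. elegans*, zebrafish,
*Drosophila* — routinely packs many visually similar, highly deformable
individuals into one frame. Estimating every animal's 2D skeleton in such
scenes defeats the usual two-stage recipes: top-down methods pay a detector
pass per animal and inherit its box errors; bottom-up methods detect
keypoints globally and then struggle to group them when bodies overlap.
`structpose` implements a single-stage alternative: every animal is
anchored by one center-heatmap peak, and its keypoints are regressed
directly from that anchor, so no detection or grouping post-processing
exists at all.

## Hierarchical pose grouping and two-hop regression

Each species schema organizes the $K$ keypoints into $P$ anatomical parts
(worm: 5 parts x 1 keypoint; fish: 5 parts, 10 keypoints; fly: 9 parts, 26
keypoints). Regressing a long displacement from the body center to, say, a
fly's tarsus tip is hard; the model therefore splits it into two hops

$$\vec{\mathrm{off}} = \vec{\mathrm{off}}_1 + \vec{\mathrm{off}}_2,$$

center $\to$ part point (one per part, predicted by the convolutional Part
Perception head from the stride-4 feature map) and part point $\to$
keypoint. The part points are *adaptive*: they are never supervised
directly. Only the sum of the two hops is penalized (an L1 loss against
the ground-truth center-to-keypoint displacement), so the network is free
to place part anchors wherever they help. The test suite asserts this
invariance explicitly: redistributing a displacement arbitrarily between
the hops leaves the loss unchanged.

Keypoint ownership is structural, not learned: the second-hop head is a
separate linear map per part, reading that part's refined feature, so
zeroing part $p$'s features can only perturb the offsets of $p$'s own
keypoints (also asserted in the tests).

## Multi-scale feature sampling (MFS)

The backbone emits a feature pyramid $F_{1/4}, F_{1/8}, \dots$ Each level
passes through a channel-transformation block that standardizes widths
(CT1: conv–ReLU–conv; CT2 adds a normalized conv and a third conv — the
third conv stands in for a deformable convolution, for which no operator
exists in this package's dependency set). For every output cell and part,
each transformed level is sampled by bilinear interpolation at the
first-hop-shifted location, scaled to the level's coordinate frame
(pixel-centered: $x_l = (x+\tfrac12)\,s_\mathrm{base}/s_l - \tfrac12$).
Sampling is border-clamped and never raises an error. Levels are fused by
a learnable softmax-normalized scalar weight per part and level (the
additive variant; concatenation + 1x1 mix is available). Because the
sampling coordinates come from predicted offsets, gradients flow through
the bilinear weights back into the first-hop head — the sampler's
coordinate derivative is implemented and numerically verified.

Defaults follow the best configuration reported for this architecture
family: CT2, additive fusion, levels $\{1/4, 1/8\}$.

## Structure-guided learning (SGL)

The fused part features form, at every spatial cell independently, a
sequence of $P$ tokens of width $C$. One (by default) pre-norm transformer
layer — LayerNorm, multi-head self-attention, LayerNorm, feed-forward,
residuals on both blocks — lets parts exchange information: an occluded
tail token can borrow evidence from the visible mid-body token. Queries
and keys are linear projections of token + learnable part-type embedding
(a `sgl_raw_qk` switch preserves the projection-free literal reading);
values are projections of the tokens alone; attention is
$\mathrm{softmax}(QK^\top/\sqrt{d})V$ per cell. Defaults: 1 layer,
feed-forward width 512, type embeddings on, 4 heads (the head count is
never specified by the architecture's description; 4 divides every
channel width used here). With zeroed output projections the layer is
exactly the identity, which the tests use as a residual-path contract.

## Losses

Center and keypoint heatmaps use the penalty-reduced focal loss

$$L = -\frac{1}{N}\Big[\sum_{t=1}(1-\hat p)^\alpha \log \hat p
 + \sum_{t<1}(1-t)^\beta \hat p^\alpha \log(1-\hat p)\Big],
 \quad \alpha = 2,\ \beta = 4,$$

with natural logs and predictions clamped to $[10^{-6}, 1-10^{-6}]$. (The
printed form of this loss in the architecture's description omits the
leading minus, which would make it negative; the standard negated form is
implemented.) The offset loss is the masked L1 on summed hops, normalized
by the visible-keypoint count for batch-size robustness
(`normalize_offsets = FALSE` restores the bare sum). The total is the
weighted sum with all three weights 1 by default. The keypoint-heatmap
branch is auxiliary: it shapes backbone features during training and is
removed at inference; decoding never reads it, so inference outputs are
bit-identical with or without it (fuzz-tested).

## Targets, decoding, evaluation

Training targets live on the stride-4 grid. Centers are splatted as
unnormalized Gaussians (max-combined), with the peak cell forced to 1;
the spread uses the corner-heatmap quadratic-root radius at IoU floor 0.3
with $\sigma = r/3$ — the focal loss's penalty reduction presumes exactly
this Gaussian neighborhood. Centers quantize by flooring to cells; if two
instances collide in one cell the later one keeps the offset slot and the
collision is counted. Offsets are stored in output-stride units (keeps
regression magnitudes $O(10)$; decoding rescales).

Decoding extracts 3x3 local maxima above a score threshold (default
0.05), keeps the top 30 (above the densest supported scene), and composes
keypoints as $\mathrm{stride}\cdot(\mathrm{center} + \vec{\mathrm{off}}_1
+ \vec{\mathrm{off}}_2)$ with both fields read at the center cell — the
part-point shift is already baked into the features by the MFS warp; a
flag reads the second hop at the part-point cell instead. Flip testing
decodes the mirrored image, un-mirrors ($x \to W-1-x$), applies the
bilateral permutation, and averages center-matched pairs (pose-level
fusion; matching radius 16 px).

Evaluation is OKS-based: $\mathrm{OKS} = \sum_i
\exp(-d_i^2/2s^2k_i^2)\,\sigma(v_i>0) / \sum_i \sigma(v_i>0)$, with $s$
the square root of the 10%-padded tight bbox area of visible keypoints
and uniform $k_i = 0.1$ (no published per-keypoint constants exist for
these species; metrics on synthetic data are self-consistent, not
comparable to any external benchmark). AP uses score-ranked
precision–recall with 101-point interpolation over thresholds
0.50:0.05:0.95; AR is the mean recall at 30 detections per image.

## The synthetic scene generator

The generator is the package's study condition, not a tuning knob. It
emulates dense behavioral frames: plain or textured bright field, 1–4
worms/fish or 5–10 flies per frame, each instance allowed to overlap
earlier ones with probability 0.5 by default, optional blur/glare/
low-light degradations. Worm bodies are smooth random curves whose net
turn is drawn wide enough to include self-coiling, with keypoints at
arclength fractions $\{0, .25, .5, .75, 1\}$; fish are a tapered body
with an articulated tail and flank keypoints inside the body width; flies
are head/thorax/abdomen blobs with two wings and six two-segment legs.
Animal geometry scales with the canvas and is floored at half benchmark
scale so small frames hold realistically proportioned bodies. Later-drawn
instances occlude earlier ones; a keypoint whose 3-px disc is covered at
least 60% by later bodies is marked `v = 1`. Every instance draws from
its own seeded substream, so adding instances never perturbs earlier
ones.

What it does *not* emulate: real texture and optics, instance appearance
variation, locomotion physics, or video continuity. Green tests therefore
certify the algorithmic pipeline (encoding, network contracts, decoding,
metrics) and trainability on controlled scenes — not transfer to real
microscope footage.

## Numerical choices

* All network gradients come from an in-package reverse-mode tape;
  convolution (im2col + BLAS) and bilinear sampling (including coordinate
  derivatives) are compiled kernels, each verified against central
  differences.
* The CT2 norm layer uses per-image spatial statistics in both modes, so
  train and inference passes are bit-identical for equal weights.
* Peak ties break toward the smaller (row, col); center-cell collisions
  keep the later instance; out-of-frame keypoints become `v = 0` under
  augmentation; instances with no visible keypoint are skipped with a
  warning; an empty offset mask yields loss 0 with a warning; a NaN loss
  aborts training naming the branch.
* He-style initialization; the center-head bias starts at
  $\log(0.1/0.9)$ so the initial heatmap sits near the background rate.

## Training protocol and problem sizes

Defaults mirror the benchmark protocol: Adam, weight decay $10^{-4}$,
$\eta_0 = 1.25\times10^{-4}$ annealed cosine-wise to
$\eta_\min = 10^{-5}$ (the step variant — x10 drops at epochs 90 and
120 — is also provided, since the protocol describes both), rotation
$[-30^\circ, 30^\circ]$, scale $[0.75, 1.5]$, translation $[-40, 40]$ px,
flip probability 0.5.

The package's own experiments run at desk scale by design: the bundled
overfitting study trains the lightweight backbone (16 channels, token
width 16, feed-forward 32) on 20 worm scenes at 128x128 for 200 epochs
with a cosine schedule from $10^{-3}$ and no augmentation, reaching train
AP50 above 0.9 on one CPU core. Benchmark-scale settings (512/640 inputs,
HRNet-class backbone, epochs 140/280) are expressible through the same
configs but are outside what the bundled experiments claim.

## Known limitations

* The built-in zebrafish and fly keypoint names and part memberships are
  documented stand-ins for an annotation key that exists only pictorially
  upstream; users with a real key should supply their own schema file.
* No deformable convolution; CT2's third conv is an ordinary one.
* Single-frame only: no tracking, no temporal models.
* The default backbone is deliberately small; it is a contract
  (stride-keyed pyramid), and heavier backbones must be plugged in for
  real-data accuracy.
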