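---
title: "Depth-separable gated attention for medical image segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-separable gated attention for medical image segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`dsganet` implements a hybrid transformer–CNN encoder–decoder for 2-D
medical-image segmentation. Three ideas make up the method:

1. **Depth-separable gated window attention.** Self-attention is computed
   inside non-overlapping $m \times m$ windows (DWGA) and then *across*
   windows through summary window tokens (PWGA). Both carry learnable
   relative-position terms whose influence is controlled by learnable scalar
   gates, one set per head.
2. **A mixed three-branch attention (MTA) skip module** that replaces plain
   U-Net skips on encoder stages 1–3 with the fusion of a channel-attention
   map, a multi-scale spatial map, and a global patch self-attention map.
3. **A 4-stage encoder / cascaded decoder** with patch embedding, patch
   merging between stages, a 3×3-conv bottleneck at the deepest stage and a
   1×1 segmentation head.

Because no deep-learning framework is assumed, the package ships its own
reverse-mode automatic differentiation engine over base-R arrays
(`R/autograd.R`); every layer (im2col convolution, layer/batch norm, the
attention operators) is built on it and all heavy numerics go through BLAS.

# The attention operators

## Within-window attention (DWGA)

For a window of tokens $z$ with per-head projections $q_o = W_Q x_o$,
$k_p = W_K x_p$, $v_p = W_V x_p$, the output at position $o$ is

$$
D_o = \sum_{p \in N_{m\times m}(o)}
\mathrm{softmax}_p\!\left(\frac{q_o^\top k_p
 + G_Q\, q_o^\top r^q_{p-o}
 + G_K\, k_p^\top r^k_{p-o}}{\sqrt{d_h}}\right)
\left(G_{V1}\, v_p + G_{V2}\, r^v_{p-o}\right)
$$

where $r^q, r^k, r^v$ are learnable tables indexed by the in-window offset
$p-o$ (a $(2m-1)^2 \times d_h$ table per head) and $G_Q, G_K, G_{V1},
G_{V2}$ are the four scalar gates per head. Setting
$G_Q = G_K = G_{V2} = 0$, $G_{V1} = 1$ recovers plain windowed attention —
the degenerate limit the test suite exploits, comparing the production path
against an explicit-loop oracle (`brute_force_attention()`).

The $1/\sqrt{d_h}$ logit scaling is part of the standard attention operator
the construction extends; we apply it to the full gated logit.

## Cross-window attention (PWGA)

Window tokens (the per-window mean of the DWGA output by default) are layer
normalized, passed through GELU, and projected to queries and keys with
their own gated position terms indexed by the *window-grid* offset (a
$(2g_r-1)(2g_c-1)$-entry table for a $g_r \times g_c$ grid). The values are
the untransformed window feature maps themselves, so each output window is
a convex, attention-weighted recombination of whole windows; the value path
is deliberately ungated and unprojected. When a stage holds a single
window, cross-window attention is exactly the identity (one softmax weight
of 1), so the block elides the PWGA parameters there — this keeps the
"every parameter receives gradient" property meaningful.

## Block structure

One DSG-ViT block computes `y = x + W_o · PWGA(DWGA(LN(x)))` followed by
`out = y + MLP(LN(y))` with a GELU feed-forward of expansion `mlp_ratio`
(default 4). With the output projection and the MLP output weights zeroed
the block is the identity map bit-exactly, which the tests assert.

# The MTA skip module

Given a stage feature $X \in \mathbb{R}^{C\times H\times W}$:

* **Channel branch**: global max- and average-pooling over space, a
  *shared* 1×1 convolution, LeakyReLU (slope 0.01) per branch, sum,
  sigmoid: $C(X) \in (0,1)^{C\times1\times1}$. Sharing the convolution is
  what makes the two branches coincide on per-channel-constant input.
* **Spatial branch**: three parallel two-stage convolution pyramids with
  kernels 3/5/7 and paddings 1/2/3 (channels $C \to C/4 \to 1$, BatchNorm +
  ReLU after each convolution), summed and squashed:
  $S \in (0,1)^{1\times H\times W}$. We use stride 1 throughout: a stride-2
  inner convolution would contradict the declared $1\times H\times W$
  branch output shape, and the stated output shape wins.
* **Global branch**: the map is cut into $P \times P$ patches (default
  $P = 2$ on the already-low-resolution stage maps), a learnable position
  code is added (one code *per patch position* — the standard ViT choice;
  a single shared code could not encode position at all), and one
  transformer block (MHSA + MLP, pre-norm residuals) is applied before
  reshaping back to $C \times H \times W$.

The fusion is `MTA = (C ⊗ S) ⊕ G` with broadcast multiplication and
elementwise addition. With *all* learnable weights zero the output is the
constant field $0.5 \cdot 0.5 + 0 = 0.25$, asserted in closed form by the
tests. The MTA output itself (not a re-weighted copy of $X$) is what the
decoder concatenates — the fusion equation defines the skip content.

# Network assembly

Stage $s$ of the encoder runs at resolution `input / (patch_size · 2^(s-1))`
with embedding widths `dims` and `depths` DSG-ViT blocks; stages 2–4 start
with patch merging (2×2 neighbourhood concatenation, layer norm, linear
reduction to half the concatenated width). Depth presets "Base" (1,1,3,1),
"Middle-1" (2,2,6,2) and "Middle-2" (3,3,9,3) are selectable by name. A
layer norm follows the patch embedding; both norms are the usual
hierarchical-transformer conditioning and noticeably speed up early
optimization.

The deepest feature passes through a 3×3 convolution + ReLU bottleneck
(no MTA at stage 4). Each decoder step doubles the resolution (bilinear by
default; a transposed-convolution operator is available by flag since the
"2×2 upsampling operator" wording admits both readings — bilinear avoids
checkerboard artefacts), concatenates the MTA output of the matching stage
when that stage is in `mta_stages`, and applies a 3×3 convolution + ReLU.
Restoration from `H/patch_size` to full resolution is a cascade of
×2-upsample + conv + ReLU stages (`log2(patch_size)` of them) before the
1×1 class head: refining boundaries at each intermediate scale measurably
improves small-structure Dice over a single ×patch_size jump, which is why
the cascade is the default. `mta_stages` subsets reproduce the 0/1/2/3-skip
ablation variants; the empty set is a skip-free U-shape.

Window sizes default to 7 (224-type inputs tile exactly at 56/28/14/7);
per stage the effective window is `min(window, resolution)` and must divide
the stage resolution, which is validated at configuration time with an
error naming the offending axis.

# Training

The optimizer is SGD with learning rate 0.01, momentum 0.9, weight decay
0.0004 and batch size 24 — the reference protocol; desk-scale runs override
the batch size downwards (8 by default). The learning rate is constant by
default with an optional polynomial-decay flag, since no schedule is
prescribed. The loss is `0.5 · cross-entropy + 0.5 · (1 − mean soft Dice)`
over all classes, a conventional choice for this family of models (the
training objective is not otherwise specified); weights are configurable.
One master seed fans out into independent streams for weight
initialization, sample order and augmentation, so ablation variants see the
same data order. Augmentation is random horizontal/vertical flips plus
right-angle rotations, applied identically to image and mask.

# The phantom generator

`phantom_spec()` / `generate_phantom()` draw multi-organ-like slices:
several rotated ellipses of distinct mean intensity (default four, from a
large bright "liver-like" structure down to a small "pancreas-like" one) on
a darker background, with additive Gaussian noise (sd 0.05) and small
per-sample intensity jitter (±0.03), clipped to [0, 1]. Structure $k$
always occupies intensity band $k$, so class identity is learnable from
appearance; later structures occlude earlier ones and the mask records
exactly the visible pixels. Identical spec + seed reproduce samples
bit-exactly, which the dataset manifest exploits for exact regeneration.

What the phantoms do *not* emulate: anatomical shape variability beyond
ellipses, partial-volume and scanner physics, inter-slice context, and
class-imbalance extremes of real CT/MRI. Passing the desk-scale
learnability check therefore demonstrates that the architecture, gradients
and training loop work end to end — not clinical-grade accuracy.

# Numerical choices

* Softmax subtracts the per-row maximum; non-finite logits raise an error
  before the softmax rather than propagating NaNs.
* Layer norm uses eps 1e-5; batch norm tracks running statistics with
  momentum 0.1 and uses them in evaluation mode.
* Projections and position tables initialize from a truncated normal
  (sd 0.02, ±2 sd); convolutions use Kaiming-normal; gates initialize to 1
  so position terms start active.
* Window partitioning, im2col convolution and relative-position lookups are
  implemented as gather/scatter primitives with duplicate-free index sets,
  so their adjoints are direct assignments — this is what makes CPU
  training at desk scale practical.
* Bilinear upsampling uses half-pixel centres with edge clamping and is a
  fixed linear operator, so its gradient is exact.

# Desk-scale problem sizes

The package's own experiments (tests and the acceptance script) run a small
configuration: 64×64 phantoms, encoder widths (16, 32, 64, 128), heads
(1, 2, 4, 8), "Base" depths, window 4, patch factor 2, batch 8, 200
optimization steps on 64 training / 16 validation samples. The patch
factor matters: with factor 4 the finest feature map is a quarter of the
image resolution and small-structure boundary Dice saturates near 0.72
regardless of training time; factor 2 restores 2-pixel boundary
resolution, and halved widths keep the finer maps affordable on one CPU.
Structural checks at 224 and 512 pixels use the standard stage geometry
with reduced widths. These sizes were chosen so every claim is verifiable
on a single CPU in minutes; all of them scale up by configuration only.

# Known limitations

* 3-D volumes are handled slice-wise only; no volumetric context.
* The distance metrics are in pixel units; no physical spacing metadata.
* Training is single-device, full-precision, and the autodiff engine keeps
  whole-graph intermediates in memory — adequate for desk scale, not for
  224-scale training runs.
* No pretrained weights, deep supervision, or test-time augmentation.
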