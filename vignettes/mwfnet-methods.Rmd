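---
title: "Multi-view gated fusion classification of neuron morphologies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view gated fusion classification of neuron morphologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mwfnet)
```

## The problem

Neuron types differ in the geometry of their dendritic and axonal arbors:
pyramidal cells carry a prominent apical trunk, basket-type interneurons a
dense local plexus, and so on. Digital reconstructions stored in the SWC
format describe an arbor as a tree of 3D points, which is sparse, irregular
and awkward for volumetric networks. `mwfnet` instead classifies a neuron
from several 2D binary projections of its arbor: the reconstruction is
rotated through a fixed grid of angles and each rotation is rendered as a
silhouette-like line drawing. View-level features are then pooled, weighted
by a learned per-view *discriminability score*, de-redundified through a
gated pairwise-similarity matrix, and fused into a single instance-level
descriptor that a small fully connected head classifies.

## Pipeline and model

### Projection

For a morphology $V = \{v_1,\dots,v_n\}$ the coordinates are first aligned
by PCA: centered, rotated onto the covariance eigenvectors sorted by
decreasing eigenvalue (largest variance $\to x$). Because an eigenvector is
only defined up to sign, each axis is oriented so the skewness of the
projected coordinates is nonnegative; if the skewness is numerically zero
($<10^{-9}$) the largest-magnitude loading is made positive instead. This
yields one canonical frame per neuron, so similar arbors produce similar
views regardless of their original orientation. Degenerate (colinear or
coplanar) clouds are harmless: the symmetric eigendecomposition still
returns a complete orthonormal basis.

View $k$ ($k = 0,\dots,N-1$, $N = \lfloor 360/\varphi\rfloor$) rotates the
aligned coordinates about the $y$-axis by $\theta_k = k\varphi$ and then
about the $z$-axis by the same angle (right-handed, active, column-vector
convention; the $y$-rotation is applied first), and projects orthographically
onto the $x$–$y$ plane. The default interval is $\varphi = 45^\circ$, giving
$N = 8$ views. Each view is min–max scaled isotropically (aspect ratio
preserved) into a square raster with a 5% margin and drawn as a binary image:
every node is plotted and every child–parent segment is traced with an
8-connected digital line (one-pixel strokes by default; SWC radii are
ignored, since a binary silhouette carries no thickness semantics). A
zero-extent morphology renders a single centered foreground pixel.

### View encoding

Each view passes through a shared convolutional backbone producing a raw
feature map $F \in \mathbb{R}^{C\times H\times W}$. The backbone is a
*contract*, not a fixed network: any deterministic map from an image to a
nonnegative feature map fits. The package ships a small two-convolution
extractor ($3\times3$ kernels, stride 2, ReLU) trained jointly with the rest
of the model; its channel widths are configurable
(`backbone_channels`, default `c(8, 16)`). The model's mathematics — pooling,
gating, fusion — is independent of the backbone's depth.

Each channel is reduced by learned generalized-mean (GeM) pooling,

$$ f_c = \Big( \tfrac{1}{|\chi_c|} \sum_{x_i \in \chi_c} x_i^{p_c}
\Big)^{1/p_c}, $$

which interpolates between average pooling ($p_c = 1$) and max pooling
($p_c \to \infty$). The exponent is learnable, initialized at 3, shared
across channels by default (`gem_per_channel = TRUE` switches to one
exponent per channel). Entries are clamped at $10^{-6}$ before the
fractional power, and the mean is computed in max-factored form
($f_c = m\,(\overline{(x/m)^p})^{1/p}$ with $m$ the channel maximum) so that
arbitrarily large exponents stay finite. After each Adam step the exponent is
clamped at $0.1$ — a projected step, chosen over reparameterization for
transparency. A batch-normalization layer maps the pooled descriptors into a
unified space; in eval mode it is a deterministic affine map through frozen
running moments.

### Discriminability scores (gated view measurement)

Views differ in how much class-relevant morphology they show. A per-view
weight $d_n \in (0,1)$ is computed from the *salient* part of the raw map:
$F$ is min–max normalized to $[0,1]$ (over the whole view by default; per
channel optionally) and entries below a threshold $T_1$ (default 0.9) are
zeroed, the boundary value being kept. A small head — $1\times1$ convolution
halving the channels, flatten, batch normalization, fully connected layer to
a scalar $s$ — is squashed through

$$ d = \sigma(\log(|s| + \varepsilon)), $$

whose absolute value and logarithm keep the sigmoid argument in its
unsaturated band for $|s|$ within several orders of magnitude of 1. The
stabilizer $\varepsilon = 10^{-12}$ only defines the score at $s = 0$. The
scores are used as-is (not renormalized over views) when fusing.

### Gated view enhancement

Rotational neighbours often show near-identical silhouettes; mixing them
naively duplicates information. Three transform layers $L_1, L_2, L_3$
(each a $1\times1$ convolution $C \to C$ with bias plus batch
normalization) map the descriptors into a common space and the pairwise
similarity matrix is the row softmax
$a_{ij} = \mathrm{softmax}_j\!\big(L_1(x_i)^\top L_2(x_j)\big)$ (unscaled dot
products; no attention temperature). A threshold $T_2$ (default 0.8)
partitions the matrix into a high-similarity mask $M_1 = I(A \ge T_2)$ —
boundary included — and its exact complement $M_2$. The gated modification
uses $e^{-a_{ij}}$ where $M_1$ holds and $e^{a_{ij}}$ where $M_2$ holds,
followed by a row softmax, so redundant pairs lose mass and dissimilar pairs
gain it. The printed composite form of this rule
($1/e^{A\odot M_1} + e^{A\odot M_2}$) lets the masked-off branch leak a
constant $e^0 = 1$ into every entry; the package implements the two-branch
elementwise reading, which matches the rule's stated intent, and keeps the
literal form available behind `eq6 = "as_printed"` for comparison. The
enhanced descriptors are $X' = A' L_3(X)$.

### Fusion and classification

The instance descriptor is the weighted sum $X_t = D X'$ (a $1\times N$ by
$N\times C$ product), optionally plus a residual connection from the mean raw
descriptor, followed by batch normalization ("residual batch normalization";
both pieces are toggleable via `residual` and `fusion_bn`). A manual weight
vector can replace $D$ entirely (`manual_weights`), which is how the
equal-weight and hand-assigned ablations are run. The classifier is two
fully connected layers of width 200 with one ReLU between them, a final
affine map to the $K$ classes and a softmax; training minimizes
cross-entropy with Adam (learning rate 0.001, batch 16).

With both gates disabled the model reduces exactly to the baseline fusion
path: unit weights and identity enhancement. The test suite asserts this
reduction by reproducing `predict()` from the exported operations alone.

## Training engine and numerical choices

No deep-learning framework is used: forward and backward passes are written
in base R. Convolutions are computed as sums of small matrix products over
kernel offsets with precomputed index maps; all gradients are derived by
hand, including the exact backward pass through the min–max normalization
(scatter terms to the argmin/argmax entries, skipped when the minimum is the
ReLU floor 0, where the minimum is locally constant). Threshold masks and
ReLU gates use the standard subgradient convention (treated as constants).
The test suite validates every parameter group against central finite
differences at relative tolerance $10^{-3}$; observed agreement is
$\sim10^{-6}$. Biases feeding directly into a batch-normalization layer
provably receive zero gradient (the batch mean removes them); they are kept
for parameter-count fidelity but exempted from the gradient-flow smoke test.

Batch normalization uses biased batch moments in training, running moments
(momentum 0.1, $\varepsilon = 10^{-5}$) in eval; eval-mode prediction is a
deterministic function of the fitted object. All randomness — growth of
synthetic morphologies, initialization, batch shuffling, fold assignment —
flows through explicitly derived 32-bit sub-seeds, so identical
configuration and seed reproduce reports bit-for-bit on CPU.

## Synthetic morphologies

Because curated repositories cannot be bundled, the package generates
labeled morphologies whose classes differ in branching statistics. A tip
elongates in steps of Gaussian-jittered length whose direction blends its
previous heading (inertia 0.7), a class-level trunk bias (0.15) and
isotropic noise (0.3); after each step it bifurcates with probability
`branch_prob` (opening half-angle jittered around `branch_angle_deg`) until
`max_depth` bifurcation levels, and a section terminates after `n_steps`
steps. The `separable-3` preset (sparse apical-trunk arbors at
`branch_prob = 0.04`, tufted arbors at 0.25, bushy isotropic arbors at 0.60)
yields class-mean branch counts near 2, 34 and 148 — separated widely enough
that a depth-1 decision stump on branch count alone exceeds 80% accuracy,
which is what makes the end-to-end classification check meaningful rather
than vacuous. The `confusable-2` preset (0.30 vs 0.33) deliberately
overlaps.

The generator emulates the *statistics* that distinguish morphological
classes (branch density, cable length, growth bias), not real
reconstructions: there is no soma geometry, no diameter taper, no
tortuosity model, no reconstruction noise or type-code structure. Passing
the desk-scale tests therefore demonstrates that the pipeline can learn
branching-statistic classes end to end; it does not certify accuracy on
repository data, which requires the full-scale backbone and curated
datasets.

## Desk-scale study conditions

The shipped evaluation uses 30 neurons per `separable-3` class, 64-pixel
views, the two-convolution backbone with 16 descriptor channels, 18 epochs
and stratified 10-fold cross-validation — sizes chosen once so the whole
study runs on a single CPU in minutes. Stratified folds (the round-robin
deal within each class) prevent empty-class test folds at this scale; plain
random folding is what the full-scale protocol describes, and stratification
is the standard refinement. Macro averaging is used for the reported F1
(the unweighted mean over classes); the per-class F1 vector is always
reported alongside. At these conditions 10-fold CV reaches mean accuracy
well above the 0.80 property threshold (chance 1/3), and the full gated
model performs on par with the plain fusion baseline — at desk scale the
classes are separable enough that the gates have little room to add
accuracy; their value is asserted only as "not worse", mirroring the
ablation structure of the full-scale study.

## Known limitations

* The rasterizer draws constant-thickness strokes; radius-aware rendering
  (e.g. soma discs) is deliberately out of scope.
* The GVMM head operates on the flattened masked map, so its fully connected
  layer grows with $C/2 \cdot H \cdot W$; at full scale ($C = 2048$,
  $7\times7$ maps) the published parameter budget for this head is ambiguous
  and the text-order wiring is implemented as described.
* Per-view scaling bounds are recomputed per rotation, so view $k$ of a
  pre-rotated neuron is not bit-identical to view $k{-}1$ of the original;
  the two-axis rotation scheme does not compose additively.
* Training is single-threaded CPU; the engine is written for correctness and
  desk-scale sizes, not throughput.
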