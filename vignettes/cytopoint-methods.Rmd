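---
title: "Methods: centre-point immune cell detection and counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centre-point immune cell detection and counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cytopoint)
```

This vignette documents the model, the numerical choices and the
limitations of `cytopoint`, in the spirit of a methods section: what is
computed, under which assumptions, and what a passing test does and does
not establish.

## The problem and the annotation model

A differential immune cell count classifies the leukocytes on a stained
cytospin slide into macrophage lineage (monocytes and macrophages pooled,
as is standard in cytopathology), neutrophils, eosinophils and
lymphocytes. The counting itself is a multi-class object detection
problem on brightfield tiles, with two properties that make boxes and
masks awkward: cells frequently touch or overlap, and cell boundaries are
often low-contrast. Cell *centres*, in contrast, essentially never
coincide. `cytopoint` therefore treats a single click at the centre of
the whole cell as the full annotation, and everything else — object size,
class appearance, detection — is modelled around these points.

Coordinates are 0-based, x rightwards, y downwards, real-valued (sub-pixel
clicks allowed), at the native tile scale (nominally 1024 px at ×100
magnification).

## Consensus of multiple assessors

Assessors disagree, so ground truth is built by merging their click sets:

* all clicks on a tile are clustered by **single-linkage connected
  components** of the "pairwise distance ≤ 10 px" graph. Single linkage is
  the faithful reading of a plain "within a radius" rule, is
  permutation-invariant, and is verified in tests against a brute-force
  components-of-the-adjacency-graph oracle. A greedy nearest-first
  alternative is available (`method = "greedy"`).
* each cluster becomes one consensus point at the **arithmetic centroid**
  of its members (the rule is not otherwise determined; the centroid is
  the least-commitment choice and keeps merging idempotent).
* the cluster's class is the **modal vote**. Exact ties are never resolved
  automatically: they are emitted with `resolution = "flagged_tie"` for
  the expert-review pass that a production annotation workflow includes,
  with a deterministic placeholder class (first tied class in configured
  order) so downstream code is total. A cluster containing two points
  from the *same* assessor is treated as an ordinary vote — the data
  gives no reason to privilege either click.

## Class sizes and Gaussian targets

Each class has a reference diameter: the median of manual width
measurements across the longest span per object (142 px macrophage
lineage, 104 px neutrophil, 126 px eosinophil, 61 px lymphocyte at native
scale). The median rather than the mean is used because the measured
distributions are skewed (alveolar macrophages especially) and the
published summaries are medians. The heatmap spread is the class
*radius*, `sigma_px = diameter_px / 2`, configurable via
`class_config()`.

`encode_targets()` renders, per class channel,

\[ K_{\sigma_c}(x, y) = \exp\!\left(-\frac{(x - x_0)^2 + (y - y_0)^2}
   {2\,\sigma_c'^2}\right) \]

at every centre, with all geometry divided by the `scale_factor` between
native tile and network resolution (4 for 1024 → 256). Numerical
choices:

* the kernel is evaluated at the **real-valued rescaled centre** — no
  rounding before evaluation — and truncated beyond `4σ'` (dropped values
  are < 3.4e-4);
* the nearest pixel to the centre is then set to **exactly 1**. The focal
  loss distinguishes its positive branch by `Y == 1`, so exact-1 support
  must exist; this also makes "one annotation ⇒ unit peak" hold for
  sub-pixel clicks.
* overlapping kernels combine by **element-wise maximum**, not summation:
  the sum of two nearby kernels would exceed 1, violating `Y ∈ (0,1)` and
  destroying the unit-peak property at both centres. Whether the original
  implementation summed or maxed is not stated; max is the standard
  choice in keypoint detection.

## Peak decoding

`decode_peaks()` inverts the encoding at inference time: per channel,
pixels with score > 0.5 are grouped into 8-connected components
(4-connectivity is a flag); each component with area ≤ 16 px² emits one
prediction at its maximum pixel (ties broken to the lowest `(y, x)`,
deterministically), scored by that maximum, rescaled back to native
coordinates at pixel centres.

Components *larger* than 16 px² are not specified by the published
decoding rule. Discarding them silently would make wide, well-formed
Gaussian peaks (large classes, σ' > 2) undetectable, so the default
(`oversized = "split"`) extracts the regional maxima of the component,
greedily thinned so accepted maxima are at least one class radius apart;
`oversized = "discard"` restores the strict reading. A consequence worth
knowing: with any one-peak-per-cluster decoder the prediction count is
*not* globally monotone in the threshold on arbitrary noise images (a
rising threshold can split a component); it is monotone on well-formed
encoded/predicted heatmaps, and the property test exercises exactly that.

## Network

The detector is a fully convolutional encoder–decoder producing C
heatmap channels at input resolution, values strictly in (0,1) via a
logistic output. The decoder is 5 upsampling blocks — sub-pixel (pixel
shuffle) ×2 upsample, then two 3×3 convolutions each followed by batch
normalization — with skip connections (by concatenation) from the
matching encoder resolutions. Two encoder presets exist:

* `resnet34_like`: a 34-layer residual encoder, widths 64/128/256/512,
  basic blocks 3/4/6/3, downsampling by strided 3×3 convolution (the
  max-pool of the textbook stem is replaced by a strided convolution;
  same geometry, one less primitive to maintain);
* `tiny`: a ~10-layer residual encoder, base width 16, ~0.3 M parameters,
  sized so CPU training on 64-px tiles takes minutes. It exists so that
  the learning dynamics of the full method are testable at desk scale.

There is no autodiff framework in this R stack, so forward and backward
passes are hand-written (im2col + BLAS matmul convolutions in Rcpp,
batch-norm with exact train-mode backward, pixel-shuffle as index
permutation). Correctness is enforced by finite-difference tests: the
loss gradient on a 4×4 instance to 1e-4, and a whole-network directional
derivative (the residual ReLU kinks limit finite-difference accuracy to
~1e-3 relative at h = 1e-6, which the test tolerance reflects).

The head bias is initialised to `qlogis(0.1)` so the initial heatmap
predicts the ~10 % foreground prior — the standard stabiliser for focal
losses; without it early training is dominated by the background term.

## Loss

The penalty-reduced focal loss over all pixels, classes and batch items:

\[ L = \frac{-1}{N} \sum_{xyc}
   \begin{cases}
   (1-\hat Y)^{\alpha}\,\log \hat Y & Y = 1\\[2pt]
   (1-Y)^{\beta}\,\hat Y^{\alpha}\,\log(1-\hat Y) & \text{otherwise}
   \end{cases} \]

with natural logarithms, `N` = number of exact-1 centre pixels clamped to
≥ 1 (so empty tiles contribute a pure background loss), and predictions
clamped to `[1e-6, 1 − 1e-6]` before logs. `β = 2` is the published
setting. `α` was described only as "set with reference to the number of
objects", which is not a formula; the default here is `α = 2`, the
keypoint-detection convention from which the loss originates, and it is
exposed in the configuration. The `(1−Y)^β` factor is the "penalty
reduction": background pixels inside a Gaussian bump are barely
penalised for firing, which is what lets neighbouring cells keep
distinct peaks.

## Training

Adam with decoupled weight decay (1e-5, on convolution weights only), a
one-cycle learning-rate schedule (30 % warm-up, cosine decay to 5 % of
peak; peak 2e-3 by default), batch size 8, 60 epochs by default.
Optimiser, schedule and batch size are package choices — the published
recipe fixes only the weight decay, the epoch count and the use of a
learning-rate finder (out of scope here). Augmentation applies a random
affine map (rotation ≤ 15°, shear ≤ 0.08 as the "warp", both flips) to
*image and points jointly*, re-encodes the Gaussian targets from the
transformed points, and jitters colour gains ±10 %. Nearest-neighbour
sampling with edge clamping keeps the image codomain in [0,1]. A single
integer seed fixes initialisation, shuffling and every augmentation draw;
two runs with the same seed produce bitwise-identical loss histories on
one device.

## Evaluation

Matching: per tile and class, predictions in descending score order
greedily claim the nearest unmatched ground-truth point within
`δ × diameter_px(class)`, δ ∈ {0.1, 0.25, 0.5}; "half a cell diameter"
is δ = 0.5. The threshold scales with the *class size parameter*, not the
Gaussian σ. Greedy matching mirrors the sequential "unmatched ground
truth" phrasing of the metric; an optimal bipartite matcher
(`method = "optimal"`) is provided and is pinned to a brute-force
enumeration oracle in the tests. Greedy can in principle fall one match
short of optimal on adversarial geometry; the tests document and bound
this (≤ 1, < 5 % of random scenes) rather than pretending it cannot
happen.

AP: predictions are pooled over tiles (not averaged per tile — per-tile
averaging over-weights near-empty tiles), ranked by score, and AP is the
interpolated precision–recall area (precision at each recall level = max
precision at any higher recall). For unscored sets — human assessors
evaluated against the consensus — all scores are equal and the
definition degenerates, by construction, to precision × recall at the
single operating point; this is reported as such. The "total immune
cell" row re-matches all points class-agnostically, with each
ground-truth point keeping its own class diameter as match radius.

ICC(A,1): the single-rater two-way absolute-agreement intraclass
correlation, `(MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE))`,
computed from the two-way ANOVA mean squares. Absolute agreement (not
consistency) is the right statistic because a rater with a constant
counting bias should score below 1. A constant matrix is degenerate and
returned as 1 with a flag. The implementation is pinned to an
independent `stats::aov` decomposition at 1e-10.

Differential counts report per-class counts and percentages of total
immune cells, with the two asthma-relevant categorical determinations at
strict thresholds: eosinophilic if eosinophil % > 3, neutrophilic if
neutrophil % > 61. Percentages are rounded only for display, never
before flag evaluation, so 61.0000 % is negative and 61.004 % is
positive.

`dataset_split()` splits by cytospin, never by tile, preventing
within-slide leakage; 19 cytospins × 40 tiles with two cytospins held
out reproduces the 680-tile (89.5 %) / 80-tile (10.5 %) bookkeeping.

## The synthetic world

The generator is a *stated world*, not a tuning dial: its defaults are
the documented properties of the clinical dataset where those exist, and
explicit package choices where they do not.

* Object count: Poisson(15) truncated to [0, 43] on 1024-px tiles (the
  observed mean and range).
* Class mix: macrophage lineage 45.4 %, neutrophil 45.35 %, eosinophil
  4.2 %, lymphocyte 5.07 % (the consensus dataset composition).
* Diameters: log-normal per class, median pinned to the class config and
  log-spread matched to the observed interquartile ranges.
* Minimum centre separation 0.4 × the smallest class diameter: touching
  and overlapping cell *bodies* occur (the motivating hard case) while
  centres stay distinct.
* Appearance is deliberately stylised — flat-shaded elliptical cytoplasm
  and nuclei, lobed nuclei for granulocytes, red-tinted granular
  cytoplasm for eosinophils, debris specks and mucus smears, two stain
  palettes with per-cytospin jitter standing in for the two staining
  protocols. The test surface needs controllable geometry and
  class-separable features; it does not need photorealism, and no claim
  about clinical-image performance follows from green tests here.

One deviation is forced by geometry: a 64-px tile cannot carry 15 cells
of self-similar size (the 1024-px density would tile the frame
completely), so small-tile configurations default to Poisson(6) truncated
to [1, 12]. Diameters scale by `tile_size / 1024`.

`simulate_assessors()` degrades truth with positional jitter, Bernoulli
misses and a class-confusion matrix, which is sufficient to reproduce
the qualitative inter-rater phenomena (ICC = 1 for perfect assessors,
ICC < 1 under bias or confusion) the inter-person variability analysis
measures.

## Scaled-down acceptance and what it establishes

Training the full `resnet34_like` model at 256 px on clinical images is
a GPU-scale task and is not reproduced. The package instead demonstrates
*parameter recovery in its own stated world*: the `tiny` preset trained
on 200 synthetic 64-px tiles (10 epochs, ~2 min/seed on one CPU) reaches
a median total-immune-cell AP(δ = 0.5) ≥ 0.7 over 3 seeds on 50 held-out
tiles — measured ~0.87 in development. The criterion's AP is the
class-agnostic pooled AP, the headline quantity of the original
evaluation. This establishes that the loss, encoding, decoding, matching
and training loop are jointly functional; it does not establish clinical
accuracy.

## Known limitations

* The PNG/TIFF codecs intentionally read only the dialects they write
  (8-bit RGB filter-0 PNG; uncompressed float32 multi-page TIFF).
* No sub-pixel peak refinement; decoded centres are pixel centres, so
  localisation error is bounded below by the rescale quantum.
* `α` constant per run; the object-count-adaptive rule hinted at by the
  original description remains an open question.
* Whole-slide (SVS) ingestion, annotation-platform integration, the
  hourglass and cross-entropy model variants, and bounding-box/mask
  comparators are out of scope.
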