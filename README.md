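# cytopoint

Centre-point ("keypoint") detection and differential counting of immune
cells on brightfield cytopathology tiles.

Differential cell counts — the proportions of macrophage-lineage cells,
neutrophils, eosinophils and lymphocytes in a respiratory sample — are
usually produced by trained assessors clicking or counting cells under a
microscope. `cytopoint` implements the full computational counterpart for
single-click annotations: each cell is marked only by one point at the
centre of the whole cell (not the nucleus), which is the cheapest
annotation modality an expert can produce, and everything downstream is
learned or derived from those points.

The pipeline:

1. **Consensus annotation.** Clicks from several assessors on the same
   tile are merged by single-linkage clustering at a 10 px dedup radius;
   each cluster becomes one consensus point at its centroid with the
   majority class (ties are flagged for expert review).
2. **Class-adaptive Gaussian targets.** Consensus points are rendered as
   per-class heatmaps `Y ∈ (0,1)^{W×H×C}` with a 2-D Gaussian kernel
   `K_σc(x, y) = exp(−(x² + y²) / 2σ_c²)` at each centre, where σ_c is the
   class radius (half the median measured diameter: 142, 104, 126 and
   61 px for the four classes at ×100 magnification on 1024-px tiles).
   Overlapping kernels combine by per-pixel maximum; the centre pixel is
   exactly 1.
3. **Model.** A fully convolutional encoder–decoder (residual encoder,
   5 pixel-shuffle upsampling blocks with two 3×3 conv + batch-norm each,
   U-Net skip connections, logistic output) maps a `256×256×3` tile to
   `256×256×C` heatmaps. Training minimises the penalty-reduced focal
   loss
   `L = −1/N Σ_xyc [(1−Ŷ)^α log Ŷ  if Y = 1;  (1−Y)^β Ŷ^α log(1−Ŷ) otherwise]`
   with β = 2, Adam + decoupled weight decay 1e-5, 60 epochs by default,
   and joint image/annotation augmentation (rotation, shear warp, flips,
   colour jitter). The network, backpropagation and optimiser are
   implemented from scratch in R (+ small Rcpp kernels); no deep-learning
   framework is required.
4. **Decoding and evaluation.** Predicted heatmaps are thresholded at
   0.5, connected components with area ≤ 16 yield one prediction at
   their maximum pixel, and predictions are matched to ground truth
   within δ × class diameter for δ ∈ {0.1, 0.25, 0.5}. The package
   reports AP (interpolated PR area over score-ranked pooled
   predictions), precision/recall/F1, two-way absolute-agreement
   intraclass correlation ICC(A,1) for inter-assessor analysis, and
   differential counts with the categorical determinations
   (> 3 % eosinophils, > 61 % neutrophils).
5. **Synthetic cytospins.** A seeded generator renders stylised
   cytospin-like tiles (class-styled cell blobs, debris, mucus, stain
   palettes) with exact ground-truth centres, so the entire pipeline is
   testable end-to-end without clinical images.

## Worked example

Train the CPU-sized `tiny` preset on the 64-px synthetic world and
evaluate it on held-out tiles:

```r
library(cytopoint)

world <- scene_config(tile_size = 64)        # scaled-down cytospin world
gen <- function(n, s0) lapply(seq_len(n), function(i) {
  tl <- generate_tile(world, seed = s0 + i)
  list(image = tl$image, annotations = tl$truth)
})
train_ds <- gen(200, 10000)
holdout  <- gen(50, 20000)

set.seed(101)
net <- build_network(model_config(64, 4, "tiny"))
net <- train_model(net, train_ds,
                   train_config(epochs = 10, batch_size = 8, seed = 101),
                   classes = world$classes)

hms   <- predict_heatmaps(net, lapply(holdout, `[[`, "image"))
gts   <- lapply(holdout, `[[`, "annotations")
preds <- lapply(seq_along(hms), function(i)
  decode_peaks(hms[[i]], classes = world$classes,
               tile_id = gts[[i]]$tile_id))
evaluate_detections(preds, gts, world$classes, deltas = 0.5)
```

Output from the run above (about 2 minutes on one CPU):

```
          cell_class delta        AP precision    recall        F1  TP FP FN n_gt
1 macrophage_lineage   0.5 0.7252336 0.9906542 0.7310345 0.8412698 106  1 39  145
2         neutrophil   0.5 0.9038521 0.9924812 0.9041096 0.9462366 132  1 14  146
3         eosinophil   0.5 0.9504132 0.9545455 0.9545455 0.9545455  21  1  1   22
4         lymphocyte   0.5 0.6153846 1.0000000 0.6153846 0.7619048   8  0  5   13
5  total_immune_cell   0.5 0.8196857 0.9925926 0.8220859 0.8993289 268  2 58  326
```

Each row is one class at the δ = 0.5 match radius (half a class
diameter): the detector finds 82 % of all planted cells with 99 %
precision after ten epochs; the rare small lymphocytes are, as for human
assessors, the hardest class.

Differential counting and the categorical flags:

```r
dc <- differential_count(gts)
dc
#> <differential count> total 326 cells
#>           cell_class count percent
#> 1 macrophage_lineage   145    44.5
#> 2         neutrophil   146    44.8
#> 3         eosinophil    22     6.7
#> 4         lymphocyte    13     4.0
#> eosinophilic (>3%): TRUE   neutrophilic (>61%): FALSE
```

The command line mirrors the same stages
(`simulate → consensus → encode → train → predict → evaluate → count`):

```sh
Rscript exec/cytopoint simulate --config sim.yaml --out tiles/ --seed 1
Rscript exec/cytopoint train    --config train.yaml --out model/ --seed 1
Rscript exec/cytopoint predict  --config pred.yaml  --out pred/
Rscript exec/cytopoint evaluate --config eval.yaml  --out report/
```

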