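# polarswarm

Unsupervised segmentation of star-convex organs (hearts, ventricular
cavities) in 2-D grayscale CT/MR-like images, for image-analysis
researchers who need an initialization-free active-contour method with a
shape prior and a full validation suite.

## Method

The pipeline has three stages:

1. **Shape-prior template.** Expert binary shapes are aligned by per-shape
   similarity transforms (translation *a, b*, scale *s*, rotation *θ*;
   matrix `M(a,b)·H(s)·R(θ)`) minimizing the pairwise overlap energy

   E_alig = Σᵢ Σ_{j≠i} ∫(Ĩᵢ − Ĩⱼ)² dA / ∫(Ĩᵢ + Ĩⱼ)² dA,

   then superposed; the boundary of the union is the template.
2. **Placement + polar multiswarm search.** The template is placed on the
   image by maximum mutual information; the plane around the placed
   centroid is split into K polar sections (K = number of snaxels), each
   holding one particle swarm seeded from n radially scaled template
   contours that bracket the boundary. Particles are radial positions
   updated by

   vᵢ ← φ vᵢ + κ r₁ (p_best − xᵢ) + κ r₂ (p_gbest − xᵢ),  xᵢ ← xᵢ + vᵢ,

   with fitness = the Euclidean distance map of the image edge set,
   interpolated at the particle's point (0 = on an edge). The contour is
   the polygon through the K per-section bests.
3. **Validation.** Jaccard, Dice, Pearson correlation, (directed or
   symmetric) Hausdorff distance and the maximum cardinality similarity
   metric R_n = (N/(N−TP))·(TP/(TP+FN) − TP/N); plus Chan–Vese
   region/shape/image energies E_T = w₁E₁ + w₂E₂ + w₃E₃ as scores.

Clinical datasets are emulated by a seeded phantom generator (star-convex
bright blob, additive Gaussian noise), so everything is testable offline.

## Worked example

```r
library(polarswarm)

spec  <- phantom_spec(shape = "blob", radius = 30, noise_sigma = 0.05, seed = 7)
truth <- make_shape_mask(spec, c(128, 128))
img   <- render_phantom(truth, spec)$image

train <- make_training_set(spec, n = 8, frame = c(128, 128), seed = 8)
al    <- align_shapes(train$shapes)
tpl   <- build_template(al$aligned)

res <- run_segmentation(img, tpl, preset_config("ct", seed = 11))
evaluate_masks(truth, res$mask)
#> J = 0.9772  D = 0.9885  rho = 0.9861  H = 1.414 px  MCSM = 0.6444
```

Reading the output: the segmentation overlaps the ground truth with
Jaccard 0.98 / Dice 0.99, the boundary never strays more than 1.4 px from
the true edge (Hausdorff), and 64% of true edge pixels are hit exactly
pixel-for-pixel (MCSM with 0 px tolerance — strict by design; at 1 px
tolerance it is 0.99).

The same stages are scriptable from a shell:

```sh
Rscript inst/cli/polarswarm.R synth    --out demo --seed 4
Rscript inst/cli/polarswarm.R align    --shapes demo/shapes --out demo/template.png
Rscript inst/cli/polarswarm.R segment  --image demo/image.png --template demo/template.png \
                                       --out demo/mask.png --preset ct --seed 4
Rscript inst/cli/polarswarm.R evaluate --ref demo/truth.png --res demo/mask.png --out demo/report.json
```

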