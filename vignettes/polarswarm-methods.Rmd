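---
title: "Polar multiswarm segmentation with a shape prior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polar multiswarm segmentation with a shape prior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarswarm)
```

## The problem and the model

Delineating a heart or ventricular cavity on a 2-D CT or MR slice is, for a
cardiologist, a manual contouring task; for an algorithm it is a search for a
closed curve lying on the organ boundary. Classical parametric active
contours (snakes) are easily trapped in local minima and need initialization
close to the target. `polarswarm` implements an unsupervised alternative
that combines three ingredients:

1. **A shape prior built by alignment.** A training set of expert-drawn
   binary shapes is registered by per-shape similarity transforms
   (x/y-translation $a, b$, isotropic scale $s$, rotation $\theta$)
   minimizing the pairwise overlap energy
   $$E_{alig} = \sum_i \sum_{j \ne i}
     \frac{\int (\tilde I_i - \tilde I_j)^2\,dA}
          {\int (\tilde I_i + \tilde I_j)^2\,dA},$$
   with integrals taken as pixel sums over the nearest-neighbour-resampled
   binary shapes. The aligned shapes are superposed (pixelwise maximum) and
   the boundary of the union — the *maximum shape boundary* — becomes the
   template, with its foreground centroid as reference origin.
2. **Automatic placement by mutual information.** The template, rendered as
   a two-level image, is slid over the target image; the translation
   maximizing the mutual information of the joint intensity histogram fixes
   the origin of a polar coordinate system. No user interaction is needed.
3. **One particle swarm per polar section.** The plane around the origin is
   divided into $K$ angular sections of width $2\pi/K$, where $K$ is the
   number of contour control points (snaxels). The template boundary radius
   in each section, scaled by $n$ evenly spaced factors, seeds $n$ particles
   per section; the scaled contours are assumed to bracket the true
   boundary, so the section's search space is the radial interval they
   span. Each swarm independently iterates the PSO update
   $$v_i \leftarrow \varphi v_i + \kappa r_1 (p_{best} - x_i)
       + \kappa r_2 (p_{gbest} - x_i), \qquad x_i \leftarrow x_i + v_i,$$
   with $r_1, r_2 \sim U(0,1)$, against a fitness equal to the bilinearly
   interpolated **Euclidean distance map** of the image edge set (0 on an
   edge, growing away from it; lower is better). Out-of-bounds particles
   are clamped to the violated bound with velocity zeroed; non-finite ones
   are resampled inside the bounds. The segmentation is the filled polygon
   through the $K$ per-swarm best particles in section order.

A Chan–Vese energy with shape prior is provided as a configuration score:
$E_T = w_1 E_1 + w_2 E_2 + w_3 E_3$ with the region fidelity/length/area
term $E_1$, the template mismatch
$E_2 = \int (H(\phi) - H(\phi_T))^2$, and the gradient-difference term
$E_3 = \int (\nabla H(\phi) - \nabla I)^2$, where $\phi$ is a signed
distance function and $H$ a regularized Heaviside. These energies score
candidate segmentations (and can optionally augment the PSO fitness); the
package does not evolve $\phi$ by gradient flow — the polar multiswarm is
the optimizer.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `n_scaled_contours` | scaled template copies = particles per swarm | 9 (CT), 7 (MR) | more particles widen radial sampling |
| `n_control_points` | snaxels = polar sections $K$ | 45 (CT), 35 (MR) | 45 sections = 8° each |
| `iterations` | PSO iterations per swarm | 10 | fixed count; an optional stability stop (best fitness change < 1e-6 for 3 iterations) can end a swarm early |
| `inertia` ($\varphi$) | weight of previous velocity | 0.5 (CT), 0.4 (MR) | exploration vs exploitation |
| `learning` ($\kappa$) | attraction to bests | 0.9 (CT), 0.7 (MR) | scales the step size |
| `scale_range` | radial bracket around the template radius | (0.7, 1.3) | defines each section's search bounds |
| `edge_threshold` | fraction of max gradient magnitude | 0.3 | relative, so independent of bit depth |
| `smooth_sigma` | Gaussian pre-smoothing (px) | 1 | suppresses noise-induced edges |
| `epsilon` | Heaviside regularization width | 1 | arctan form; $H(0) = 0.5$ |
| `w1, w2, w3, mu, nu` | energy weights | 1, 1, 1, 0.1, 0 | scoring only |

The CT/MR presets mirror the published experimental settings for heart and
ventricle segmentation; `preset_config("ct")` and `preset_config("mr")`
expose them directly.

## Numerical choices

* **Coordinates.** 0-based (row, col) with pixel centres at integers;
  $x =$ col, $y =$ row in all transform equations. Similarity transforms
  are the ordered product $M(a,b)\,H(s)\,R(\theta)$; `apply_transform`
  applies the matrix in frame-centre-relative coordinates so rotation and
  scale pivot about the image centre rather than its corner, keeping
  modestly transformed shapes inside the frame.
* **Edges and distances.** Mask edges are the inner 4-connected boundary
  (8-connectivity by flag); frame-exterior pixels count as background.
  Intensity edges are central-difference gradient magnitudes thresholded at
  a fraction of the maximum. The distance transform is exact Euclidean
  (verified against a brute-force oracle in the tests). The signed distance
  field places the zero level between pixel centres, so innermost and
  outermost pixels sit at $\pm 0.5$ px and thresholding at zero recovers
  the mask exactly.
* **Heaviside.** The ideal step is replaced by
  $\tfrac12(1 + \tfrac2\pi \arctan(x/\varepsilon))$: the optimizer is
  gradient-free, but a defined value at $\phi = 0$ (namely 0.5) and $C^1$
  smoothness keep the energies well-behaved.
* **Alignment optimizer.** The overlap energy of nearest-neighbour-resampled
  binary shapes is piecewise constant, so analytic gradients do not exist
  and tiny probe steps sense nothing. The package therefore (i) initializes
  each shape against the anchored first shape by matching centroids and
  areas and grid-searching the rotation (the initialization is kept only if
  it lowers the energy), (ii) descends with central-difference gradients on
  a coarse-to-fine probe schedule (4x, 2x, 1x the base probes of 0.5 px,
  0.01 scale, 0.5°), and (iii) line-searches with backtracking halving
  along both gradient signs, falling back to single-coordinate probe moves,
  accepting only strict energy decreases. The energy trace is therefore
  non-increasing by construction. Anchoring the first shape removes the
  global-transform gauge freedom.
* **Tie-breaks.** Mutual-information placement searches a stride-2
  translation grid and refines at stride 1; ties resolve to the smallest
  row, then column. Equal-fitness particles keep the earlier best
  (strict-improvement updates); the swarm's global best is refreshed
  immediately after each particle evaluation, and within a particle update
  $r_1$ is drawn before $r_2$ — fixed orders that make runs reproducible
  and externally checkable.
* **Degenerate inputs.** Empty edge sets abort segmentation before any
  swarm starts; a section whose bisector ray misses the template is
  interpolated from its neighbours; constant images yield an empty edge
  mask with a warning; empty/full masks have no signed distance.
* **Randomness.** One master seed; per-section child streams are drawn once
  from it, so changing the section count or the iteration budget of one
  swarm never perturbs another's draws. Identical inputs and seed give
  bit-identical results.

## The synthetic phantoms

The clinical datasets behind the published tables are not publicly
deposited, so the package ships a phantom generator that emulates their
geometry: a bright, quasi-convex organ-like region
($r(\theta) = r_0 (1 + \sum_{k=2}^{5} a_k \cos(k\theta + \phi_k))$,
$\sum_k |a_k| \le$ the perturbation amplitude) on a darker background with
additive Gaussian noise (default $\sigma = 0.05$ on a [0, 1] intensity
scale, object 0.8 on background 0.25), plus training sets of 8 shapes made
by planted similarity transforms of the base shape — mirroring the
8-shape expert training set of the motivating application. Default problem
sizes are 128x128 phantoms (64x64 for alignment-recovery studies): large
enough that a 45-snaxel contour is geometrically meaningful, small enough
that the full pipeline runs in seconds.

Perturbations are capped below 0.5 so every phantom is star-convex about
its centre — each bisector ray crosses the boundary exactly once, which is
the premise of the one-solution-per-section radial search. Real cardiac
slices are only approximately star-convex, their boundary contrast varies
locally, and their noise is not white Gaussian; passing phantom tests
therefore validates the machinery (placement, constrained search,
assembly, scoring), not clinical accuracy.

## Design choices where the design was open

* **Particle state is one radial coordinate.** Control points live on
  section bisectors; an angular degree of freedom is deliberately not
  modelled, matching the one-edge-solution-per-section premise and keeping
  the constraint region an interval.
* **Particles per swarm equals the number of scaled contours** — each
  scaled contour contributes one seed per section, the only reading that
  makes the scaled contours "generate" the particles.
* **Fitness is the distance-map value alone by default.** The shape-prior
  energy can be added per control point
  (`fitness = "dmap+shape"` adds $w_2 \cdot \tfrac12 |r^2 - r_T^2| \cdot 2\pi/K$,
  the polar-area mismatch of that section), but the default reproduces the
  plain distance-map fitness.
* **Section count equals the snaxel count**, with angular width $2\pi/K$.
* **Swarms are independent**; no inter-section smoothness coupling is
  applied — the closing polygon is the only place sections meet.
* **Directed Hausdorff as printed.** The tabulated form is one-sided; the
  symmetric variant is available by flag. MCSM matches edge pixels exactly
  (tolerance 0 px) by default, with an optional matching radius.

## Known limitations

* Single 2-D images only; no 3-D volumes, DICOM, anisotropic spacing, or
  sequential-slice propagation.
* Objects must be roughly star-convex about the placed origin; strongly
  concave or multi-lobed targets violate the radial model (the phantom
  generator can disable star-convexity enforcement only by raising the
  perturbation cap, which is intentionally not exposed).
* Mutual-information placement searches translations only; large rotation
  or scale mismatch between template and image must be absorbed by the
  scaled-contour bracket.
* The alignment energy is non-convex; the moment-based initialization makes
  recovery reliable for moderate planted transforms (|t| ≤ 10 px,
  s ∈ [0.8, 1.25], |θ| ≤ 20°) but pathological shape sets can still stall.

## A worked example

```{r example, eval = FALSE}
spec <- phantom_spec(shape = "blob", radius = 30, noise_sigma = 0.05, seed = 7)
truth <- make_shape_mask(spec, c(128, 128))
img <- render_phantom(truth, spec)$image

train <- make_training_set(spec, n = 8, frame = c(128, 128), seed = 8)
tpl <- build_template(align_shapes(train$shapes)$aligned)

res <- run_segmentation(img, tpl, preset_config("ct", seed = 11))
evaluate_masks(truth, res$mask)
```

The same pipeline, file-based, is available from the shell via
`inst/cli/polarswarm.R` (subcommands `synth`, `align`, `segment`,
`evaluate`, `run`) with YAML configs and JSON reports.
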