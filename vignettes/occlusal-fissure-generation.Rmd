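---
title: "Generating functional occlusal pit-and-fissure depth images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating functional occlusal pit-and-fissure depth images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(occlugen)
```

## The problem

The occlusal (chewing) surface of a posterior tooth carries a network of
pits and fissures between its cusps. These valleys are functionally
important — they shape the contact with the antagonist tooth — but CAD/CAM
crown restorations built from standard tooth libraries flatten them out.
`occlugen` treats fissure reconstruction as a conditional image-to-image
translation problem: given a depth image of the defective (masked) tooth and
a depth image of its opposing tooth, generate the depth image of the missing
pit-and-fissure morphology. This vignette records the model, its
assumptions, the tunable parameters, and the design decisions taken where
the problem was genuinely open.

## Fissure feature lines on the mesh

Fissure curves are traced between user-chosen seed vertices by a
uniform-cost search over mesh edges. The per-step cost from the current
vertex to an adjacent candidate is

```
f = lambda_a * f_dir1 + lambda_b * f_dir2 + lambda_c * f_D + lambda_d * f_C
```

* `f_dir1` — angle (radians) between this step and the previous one;
  penalizes sharp turns, keeping the curve smooth.
* `f_dir2` — angle between this step and the direction from the candidate to
  the leg's goal vertex; pulls the path toward its target.
* `f_D` — Euclidean distance from the candidate back to the leg's start,
  divided by the mesh bounding-box diagonal. Together with `f_dir2` this
  keeps concatenated legs closed around the fissure.
* `f_C` — absolute difference of discrete mean-curvature magnitude across
  the step, divided by the 95th percentile of curvature jumps over all mesh
  edges; valleys are high-curvature creases, so cheap steps follow them.

The weights default to `0.75, 0.85, 0.85, 0.55`. Two normalization
decisions make these four terms commensurate (angles are naturally in
`[0, π]`; the distance and curvature terms are scaled to a comparable
range); without some such scaling, fixed weights would be meaningless
across tooth sizes.

Because `f_dir1` couples consecutive steps, plain vertex-based shortest-path
search is insufficient: the search state is the *directed edge*
`(previous, current)`, and Dijkstra runs over that state graph
(`min_cost_path()`). Ties in accumulated cost break toward the lowest
candidate vertex index, making runs reproducible. The search permits vertex
revisits in principle; on all tested meshes the optimum coincides exactly
with exhaustive enumeration over simple paths (an extra step always incurs
positive goal-angle and distance cost). Curvature is the magnitude of the
cotangent-Laplacian mean-curvature normal with barycentric vertex areas —
rotation-invariant and standard; boundary vertices inherit the value of
their nearest interior vertex, since the open one-ring formula is biased
there. `extract_fissure_loop()` chains legs through at least three seeds and
back to the first; seed selection is left to the caller (on synthetic crowns
the groove skeleton supplies seeds; there is no automatic seed detection).

## Depth images and their inverse

`project_mesh()` places a square raster `gamma` (default 1 mm) above the
mesh top, centred on the bounding box with a 5% margin, and casts one -Z ray
per pixel centre, keeping the intersection nearest the plane (the visible
occlusal surface). The plane-to-surface distance `d` maps to an 8-bit value

```
Pixel = round(255 - 255 * (d / h)^n)
```

with `h = 6.5` mm the limit plane (farther surfaces map to 0, as do ray
misses) and `n` a grey-level enhancement exponent. `n` is not arbitrary:
`select_enhancement()` projects a set of crowns over a grid of exponents and
picks the one maximizing mean Shannon entropy of the grey histogram — the
entropy rises and then falls with `n`, and the default 1.4 is the optimum
for molar depth maps. Rounding is half-up; ties in the entropy curve break
toward the smallest exponent.

The unrounded mapping is strictly decreasing on `(0, h)`, so
`distance_from_pixel()` inverts it exactly on every integer level, and
`backproject()` lifts each nonzero pixel to a 3-D point at its pixel centre.
The only irrecoverable error is quantization: at grey level `p` the local
error bound is `h/(255 n) * (1 - p/255)^(1/n - 1)` mm, which the test suite
verifies per pixel. Zero is deliberately overloaded (background *and*
beyond-limit), which is why zero pixels emit no point.

## The adversarial model

The generator is a U-Net: stride-2 4×4 convolutions halve the resolution at
each encoder stage (channel widths 64, 128, 256, then 512 capped) down to
1×1, and transposed convolutions mirror the path back up, with encoder
stage i concatenated onto decoder stage `depth - i` so fine pixel detail
survives the bottleneck. Encoder activations are leaky-rectified (slope
0.2), decoder ones rectified, and the output tanh maps to the normalized
pixel scale `[-1, 1]`. Normalization is per-channel batch normalization
(batch size 1, so effectively instance statistics); it is omitted on the
first encoder stage and on the 1×1 bottleneck where spatial statistics are
degenerate.

The discriminator scores local realism: four 4×4 conv stages (strides
2, 2, 2, 1; widths 64–512) and a stride-1 projection to one channel yield a
30×30 matrix of per-patch probabilities at 256×256 input (6×6 at 64×64).
Patch probabilities are averaged into the scalar discriminator output
*before* the logarithm. Both networks see the conditioning pair — mask and
opposing image — concatenated channel-wise with the candidate; conditioning
the fake term as well as the real one keeps the two adversarial terms
symmetric.

The training objective, with images on the `[-1, 1]` scale:

* adversarial: `log D(x, op, y)` + `log(1 - D(x, op, G(x, op, z)))`, with
  probabilities clamped by `eps = 1e-7` inside logs. The generator maximizes
  `log D(fake)` (the non-saturating form) rather than minimizing
  `log(1 - D)`; the minimax form stalls early in training when the
  discriminator wins easily.
* L1: mean absolute deviation between generated and target image,
  weight `lambda_l1 = 100`.
* perceptual: per exposed discriminator stage i (stages 2–4),
  `S_i = mean |h_i(y) - h_i(G)|`, weighted 1, 2, 2. The generator minimizes
  `lambda_pg * sum_i w_i S_i` (50); the discriminator minimizes the hinge
  `lambda_pd * max(0, m - sum_i w_i S_i)` (20, margin `m = 0.35`), i.e. it
  is rewarded for keeping real and generated features separated up to the
  margin, after which the term is inactive.

The noise `z` is realized as 50% dropout in the first three decoder stages
during training — the standard practice for conditional translation, since
an explicitly injected noise vector is typically ignored by the generator.
With `noise_mode = "off"` training is noise-free; inference never applies
dropout, so generation is deterministic.

Optimization is alternating single-sample Adam steps (D then G per sample;
learning rate 2e-4, momenta 0.5/0.999, batch size 1, 200 epochs by
default). Three ablation groups reproduce the loss study: group 1 trains
with the adversarial objective and jaw-space conditioning only, group 2
adds L1, group 3 adds both perceptual terms. At the first update, group 2
with `lambda_l1 = 0` matches group 1 exactly, and group 3 with
`lambda_pg = lambda_pd = 0` matches group 2 — a nesting the tests assert
identically.

All layers and their backward passes are implemented in the package
(verified against central finite differences); convolutions run through
precomputed gather indices plus BLAS matrix multiplies, with small compiled
kernels for the gather/scatter and the in-place Adam update. Everything —
initialization (weights N(0, 0.02), normalization gains N(1, 0.02)),
per-epoch shuffling, dropout — derives from one seed, so loss histories are
bit-identical across runs.

## Synthetic study data

No public paired dataset of (masked tooth, antagonist, fissure target)
depth images exists, so the package generates parametric molar-like crowns:

* height field = dome (2 mm, Gaussian falloff over a ~9 mm footprint)
  + 3–5 Gaussian cusps (heights 1.0–1.8 mm, sigmas 1.2–1.9 mm) arranged
  around the centre with angular jitter
  - a groove trench (depth 0.6–1.0 mm, Gaussian cross-section of sigma
  0.5–0.9 mm) along a closed polyline through the inter-cusp saddles;
* the antagonist is the z-mirrored complement offset to a prescribed
  minimum gap (default 0.5 mm) — a geometric stand-in for the jaw-space
  constraint (applying it twice returns the original surface up to a
  vertical shift);
* the mask image suppresses a central disk (55% of the crown radius by
  default); the target keeps depth values within one groove-width of the
  skeleton and zeros elsewhere, i.e. targets are depth-valued fissure
  crops, not binary masks — consistent with treating the output as
  back-projectable geometry;
* `generate_dataset()` draws per-sample seeds from one master seed and
  records a 75/25 train/test split (400 samples → 300/100), with
  byte-identical outputs across runs.

Total relief stays under `h - gamma`, so every crown pixel is visible in
the depth window. These surfaces emulate the geometry of real molars —
cusps, connected valley network, complementary antagonist — but not scan
noise, surface texture, anatomical asymmetries or multiple tooth positions.
Tests passing on them show the pipeline's machinery is correct and the
optimization converges; they do not certify clinical image quality on
patient scans, which requires real paired data and full-scale training.

## Evaluation

`psnr()` uses `10 log10(255^2 / MSE)` with an infinite sentinel at
`MSE = 0` (kept rather than capped so monotonicity in MSE is exact).
`ssim()` is the global-statistics form — means, variances and covariance of
the whole image with `C1 = 6.5`, `C2 = 58.5` — yielding one value per pair;
no sliding window is used, a deliberate dialect matching single-number
reporting. `surface_deviation()` computes exact point-to-triangle distances
signed by the side of the nearest face and reports their standard deviation
and RMS; signed distances are what make the SD of zero-mean noise equal its
sigma, and a constant offset gives RMSE equal to the offset with SD 0.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at reduced scale
chosen to exercise every code path with comfortable margins: meshes of
32–96 grid vertices per side, images of 32–128 pixels, the training smoke
study on 8 triplets at 64×64 for 200 iterations (where the training-set L1
falls to well under 70% of its initial value), and the exhaustive
path-search oracle on meshes of at most 12 vertices, where enumeration of
all simple paths is feasible. The 256×256 architecture contracts (30×30
patch matrix, shape preservation) are verified with single forward passes.

Other fixed numerical choices: probability clamp 1e-7; batch-normalization
epsilon 1e-5; Adam epsilon 1e-8 with bias correction folded into the step
size; STL vertex welding at 1e-6 mm; degenerate (zero-area) faces dropped
on load; ray/triangle inclusion tolerance 1e-9 in barycentric coordinates;
round-half-up pixel quantization.

## Known limitations

* Output is an image, not a surface: turning generated fissures into a
  deformed crown mesh (meshing the back-projected cloud, energy-based
  surface deformation) is outside the package's scope.
* Seed vertices for fissure extraction are user-supplied.
* One projection direction (+Z occlusal view); posture normalization is
  assumed done upstream, or supplied as a rigid pre-transform.
* The discriminator patch stack needs at least 32×32 inputs; the generator
  requires power-of-two resolutions.
* Training at 256×256 full scale is computationally heavy in this
  implementation; the package targets method-scale studies, not production
  training.
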