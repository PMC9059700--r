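---
title: "fundoprep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fundoprep: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records how each stage of the package works, which parameters
matter, and the design decisions taken where more than one reasonable
reading existed. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## The screening problem

Multi-label chronic ocular disease screening assigns to each patient eight
binary flags — Normal, diabetic retinopathy, glaucoma, cataract, AMD,
hypertensive retinopathy, pathological myopia, other — from a pair of
colour fundus photographs. Performance hinges less on the classifier than
on what the classifier is shown: raw fundus frames are dominated by black
camera background, uneven illumination and fine vasculature, so the
pipeline's preprocessing stages (crop, enhance, vessel handling,
augmentation) are the object of interest here, each exposed as an
independent, testable operator.

## Region-of-interest segmentation

`detect_circles()` implements a gradient circular Hough transform on the
luma (BT.601) conversion of the input. Sobel gradients are computed with
replicated borders; pixels whose gradient magnitude reaches
`gradient_threshold` (default 50 intensity units — strong edges only, which
on an 8-bit fundus image means the disc rim and the sharpest vessels) vote
along both senses of their gradient direction at every radius in
`[min_radius, max_radius]` (defaults `⌊min(H, W)/4⌋` and `max(H, W)`).
Accumulator peaks are 3×3 local maxima above `accumulator_threshold`
(default 30 votes), greedily suppressed to pairwise centre distances of at
least `min_center_distance` (20 px). Two refinements give sub-pixel
estimates: centres are the accumulator-weighted centroid of a 5×5 window
around each peak, and the radius is the mean of edge distances within ±2 px
of the most supported distance bin. Without them, the 1-px quantisation of
centre and radius makes repeated cropping walk by up to 3 px per side;
with them crop→crop is stable to 2 px, which the test suite asserts.

Candidate choice is not "largest vote wins": the selected circle is the
highest-scoring candidate whose clamped bounding box, expanded by
`outside_margin` (5) rows/columns, contains every pixel brighter than
`nonzero_threshold`. If no candidate qualifies, the one excluding the
fewest non-zero pixels wins, ties broken toward the larger radius —
losing background is cheap, losing retina is not. `nonzero_threshold`
defaults to 0 (a strictly black background); real JPEG material and the
synthetic generator's noisy background warrant a small positive value, and
the package's own tests use 19 because the generator guarantees background
below 20 (see below). The final crop is the circle's bounding box clamped
to the frame, then resized to 256×256; cropping precedes resizing so
lesion scale is preserved. When no circle is found, the fallback is the
tight bounding box of non-zero pixels (whole frame if the image is empty),
flagged `method = "fallback"`.

The Otsu baseline (`otsu_contour_crop()`) thresholds the luma image with
Otsu's criterion, keeps the largest 8-connected foreground component and
crops to its bounding box. On well-exposed discs it agrees with the Hough
crop to a few pixels; on dark images whose disc barely clears the
background it clips — which is precisely why the Hough route exists, and
why the baseline is kept available for comparison.

One stated parameter is unattainable in a corner case: a maximum radius of
`max(H, W)` cannot be reached for heavily clipped discs whose visible arc
subtends less than a quadrant; the radius estimator simply never finds
support there, and the candidate is dropped.

## Enhancement operators

**CLAHE.** Implemented from the per-tile histogram definition so its
contract is explicit: within each tile the intensity histogram over `L`
levels is clipped at `clip_limit · n_tile / L` (clip limit 2 by default),
the clipped excess is redistributed uniformly over all bins, and level `v`
maps to `⌊(L−1) · CDF(v)⌋` with the inclusive CDF. Outputs are bilinearly
interpolated between the four neighbouring tile mappings. Consequences
worth knowing: a flat tile stays flat (the redistribution makes the
mapping approximately the identity rather than saturating at `L−1`), each
tile mapping is monotone, and with a single tile and no clipping the
operator reduces to plain histogram equalization — the form the test
suite's hand-evaluated 4×4, `L = 16` oracle checks. The tile layout is
read as a 5×5 *grid of tiles*, not 5×5-pixel patches: at the working
resolution of 256×256, 5-px tiles would equalize over 25-pixel
neighbourhoods and amplify noise to the point of uselessness, while a 5×5
grid gives ~51-px tiles, the scale of the structures being enhanced. RGB
input is equalized per channel.

**Gaussian unsharp blend.** `α·I + β·(G_σ ∗ I) + γ` with
`α = 4, β = −4, σ = 10, γ = 128`, clipped to [0, 255]. Because
`α + β = 0`, a constant image maps exactly to `γ`; the package treats this
closed form as a hard contract and therefore implements the separable
Gaussian convolution in-house with mirror-reflected borders and kernel
half-width `⌈4σ⌉`. The convolution subtracts the image mean before
filtering and adds it back, so the constant-image identity holds to the
last bit rather than to kernel-normalisation rounding.

**Multiscale retinex.** Per channel,
`raw = Σ_n W_n (log(I + ε) − log(G_{σ_n} ∗ I + ε))` with scales
`(5, 35, 150)`, equal weights and `ε = 1` (the 8-bit convention; it
avoids log 0 with a bias of at most one intensity level). The raw map is
min-max rescaled to [0, 255]; a constant raw map (constant input) is
defined as all zeros rather than dividing by a zero range. Per-channel
operation was chosen over intensity-only because the operator's users
feed RGB networks; the configuration object leaves the choice open.

## Vessel operations

Vessel segmentation is a backend contract: any function mapping an image
to a same-size intensity raster can stand behind `segment_vessels()`, so a
trained neural segmenter drops in without touching the rest of the
pipeline. The built-in `"naive"` backend — CLAHE on the green channel,
grayscale black-tophat with a disk of radius 5, global threshold 14 — is a
classical stand-in whose only job is to produce plausible masks on
synthetic and real images; it is not a clinical-grade segmenter, and the
test suite holds it only to recovering at least half of the true vessel
pixels on generated images.

Mask cleanup applies the two rules in the stated order: intensities below
20 are zeroed first, then 8-connected components smaller than 100 px are
zeroed. The boundary is sharp — a 100-px component survives, 99 px does
not — and the order matters: thresholding first can split a large dim
component into small bright fragments that the size filter then removes.
8-connectivity is the default because vessels are thin and frequently
diagonal; 4-connectivity would sever diagonal runs into sub-100-px
fragments. Both are available. The size rule operates on the thresholded
intensity mask directly (no separate binarization step), matching the
cleanup's role between a soft segmenter output and a binary mask consumer.

Inpainting replaces masked pixels with the harmonic interpolant of their
surroundings (Jacobi iteration of the Laplace equation, tolerance 0.05
intensity units, cap 500 iterations), initialised at the unmasked mean.
For the thin structures vessels are, diffusion fill converges in tens of
iterations and only ever writes inside the mask. A generative inpainting
model can replace it behind the same interface.

## Labels, augmentation, ensembling

Keyword relabelling is case-insensitive substring matching of ordered
patterns over comma-separated phrases. Pattern order encodes specificity:
`hypertensive retinopathy` maps to H and must not fall through to a
generic retinopathy pattern, which is why the DR patterns are the explicit
diabetic forms. Unmatched phrases go to the catch-all O class by default
(screening datasets bundle dozens of rare diagnoses there) or raise in
strict mode. The two-eye union keeps disease bits from either eye and the
Normal bit only when both eyes are Normal-only; declared-label mismatches
are warned about, never silently corrected. Patient-level score
aggregation is the label-wise maximum, which degrades gracefully to a
single eye — a deliberate property, since a screening visit does not
always produce both photographs.

Augmentation emits, per image, the original, horizontal flip, vertical
flip and one uniform random rotation in ±30° (bilinear, zero fill). The
±30° default reflects that fundus orientation varies modestly around the
optical axis in practice; flips are anatomically safe for laterality-blind
screening. Angles are drawn once per batch under the configured seed, so a
batch is reproducible byte for byte. Expansion is offline (a 4× larger
list); an on-the-fly regime can be had by calling `rotate_random()` per
epoch with varying seeds.

Ensembling is majority voting over exactly three binary label matrices
(2-of-3 per cell) — voting on binarized labels, not averaged scores,
because "majority rule" is a label-level notion; score averaging is
available to callers by simply averaging before `binarize()`. Odd larger
panels are allowed behind the `k` flag; even panels are rejected so no
cell can tie.

## Models, loss, metrics

`build_classifier()` represents each of the eleven supported ImageNet
backbones as a layer-by-layer parameter-accounting table (every
convolution, batch norm and dense layer with its exact shape), with the
final classification layer replaced by a fresh `d → 8` dense head. The
variants are pinned to the ones whose head-swap arithmetic matches the
published per-model counts: SqueezeNet v1.1, GoogLeNet without auxiliary
heads, Inception v3 *with* its auxiliary branch and the auxiliary
1000-way classifier retained (replacing only the main head is the standard
fine-tuning idiom), MobileNetV2, DenseNet-121, EfficientNet-B3/B7 with
width/depth multipliers (1.2, 1.4)/(2.0, 3.1) and channel rounding to
multiples of 8, ResNet-50/ResNeXt-50 32×4d/Wide ResNet-50-2 bottlenecks,
and VGG-16 without batch norm. `count_parameters()` is the column sum of
that table — a structural computation, so the head-swap identity
`count(C) = count(1000) − (d·1000 + 1000) + (d·C + C)` is checked as an
invariant rather than assumed.

No deep-learning framework is a dependency of this package. The runnable
part of a classifier is a deterministic 64-dimensional image descriptor
(coarse colour grids, moments, quantiles, bright/dark fractions, gradient
texture, radial ring statistics), a seeded random projection to the
backbone's penultimate width `d`, and the trainable head. That is enough
to exercise the loss, the metrics, aggregation, ensembling and the
end-to-end pipeline at desk scale; it is explicitly not a CNN and makes no
claim to its representational power.

The loss is the multi-label one-versus-all max-entropy form: mean over the
batch of `−(1/C) Σ_i [y_i log σ(ŷ_i) + (1−y_i) log(1−σ(ŷ_i))]`, computed
via softplus so it is stable for raw scores of magnitude 100. At `ŷ = 0`
it equals `log 2` regardless of the targets — a useful calibration point
the tests pin down. Training is full-batch gradient descent on the head
(default 25 steps per reported epoch, learning rate 0.5); with a zero
learning rate the loss trace is constant, and the whole procedure is
deterministic under its seed.

Metrics follow the macro form: precision and recall are per-class ratios
averaged over the 8 classes, and F1 is the harmonic mean *of the macro
averages* (the per-label-then-average alternative is behind `f1_mode`).
Degenerate 0/0 ratios are defined as 0 with a warning. Kappa is the
unweighted mean of per-label Cohen's kappa from each label's 2×2 table;
when chance agreement is exactly 1, kappa is defined as 1 for perfect
agreement and 0 otherwise. AUC is the per-label trapezoidal ROC area
(computed as the tie-corrected Mann–Whitney statistic, which is the same
number), macro-averaged over labels that have both classes present;
single-class labels are skipped with a warning. Score binarization uses
`score ≥ 0.5 → 1`, including the boundary.

Two scorers coexist deliberately. The macro-F1 above is the evaluation
metric; the *per-decision* `challenge_score()` — the fraction of correct
record×label cells — reflects the granularity at which a 500-patient,
8-label screening challenge credits a submission, under which exactly one
correct decision scores 1/4000 = 0.00025. `scripts/acceptance.R`
recomputes that number from scratch.

## Grad-CAM

`gradcam()` takes the last convolutional layer's activations and the class
score's gradients with respect to them as plain arrays (the
backend-agnostic hook that keeps the module testable without a trained
network). Channel weights are the spatial means of the gradient maps; the
weighted activation sum is rectified *before* normalization — clipping
negatives first is what makes the map class-discriminative — then min-max
scaled to [0, 255] per image (a constant raw map becomes all zeros) and
bilinearly resized to the image. The mask is exactly
`normalized ≥ 100`, so any positive rescaling of the raw map leaves the
mask unchanged. Contours (boundary pixels of 8-connected mask components)
are drawn green when the prediction score is ≥ 0.5, red otherwise, on a
copy of the image that differs from the input only on contour pixels.

## The synthetic generator

`generate_fundus()` renders what the pipeline's geometry exploits: a
bright disc of radius ≥ image/8 (default 0.42·min(H, W)) with a 1-px
anti-aliased rim, a radial shading profile with an optional lateral
illumination gradient, a bright optic-disc region with a darker macula
opposite, branching width-1–3 vessel random walks rooted at the optic
disc, and per-disease lesion stamps (bright exudates and drusen, dark
haemorrhages and microaneurysms, flame streaks, an enlarged cup, a myopic
crescent, a grey patch, a global cataract veil). The background is strict
zero plus Gaussian noise truncated below 20, so "non-zero pixel" rules and
the intensity-20 mask threshold are exercised against a known bound; the
1-px rim is excluded from that bound. Width 1–3 vessels give connected
components of controllable pixel count, which is what makes the 100-px
component filter testable with known truth. Rendering is byte-identical
under a fixed seed, and RNG state is always restored, so the generator
never perturbs a caller's stream. A vessel-free twin
(`render_vessels = FALSE`) consumes the identical random stream, giving a
pixel-exact reference for inpainting quality.

`generate_dataset()` emits two-eye patients: the left eye carries the
drawn condition, the right eye carries it with probability 1/2 (otherwise
normal), keywords come from a fixed vocabulary shared with the default
keyword map, and the manifest's final label is the verified union — so
relabelling a generated manifest must verify at 100%, which the tests
assert. Class mixes are sampled per patient, landing proportions within
binomial error of the request.

What the generator does *not* emulate: real optical blur and JPEG
artefacts, the anatomical correlation structure of vessels (walks are
memoryless), graded disease severity, inter-eye correlation beyond the
50% rule, and photographic variability of colour balance. Passing tests
on synthetic data therefore demonstrate the operators' contracts —
geometry, thresholds, determinism, metric arithmetic — not clinical
performance.

## Problem sizes and numerical choices

The test suite runs at sizes chosen to keep the full suite under a couple
of minutes of CPU: 256×256 images for geometry tests, 64–96 px for bulk
dataset tests, 50 seeded images for the disc-recovery study (the package
asserts IoU ≥ 0.90 against the true disc box in at least 45 of 50, and
the 5-px margin rule in all non-fallback cases), and a 300-patient /
96-px / 2-epoch end-to-end smoke run whose held-out macro-F1 must beat
the all-Normal baseline. Tolerances that matter: crop idempotence 2 px
per side; rotation-by-zero identity within 1 intensity level; inpainting
convergence at 0.05 intensity units; CLAHE constant-image flatness within
integer rounding. Tie-breaks: circle selection prefers larger radii;
component labels are assigned in column-major first-occurrence order.

## Known limitations

The naive vessel backend under-segments the thinnest vessels and is
sensitive to its global threshold; it is a stand-in, not a result. The
Hough detector assumes one dominant circular boundary and can be misled
by images containing several bright circles of comparable support —
`select_fundus_circle()`'s margin rule resolves most such cases but
depends on a background that is actually dark. The desk-scale classifier
head cannot learn spatially fine lesions the 64-dimensional descriptor
does not encode. The relabeller is substring matching, not clinical NLP:
vocabulary outside its pattern list lands in the catch-all class.
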