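# fundoprep

Preprocessing, augmentation and evaluation building blocks for multi-label
**chronic ocular disease (COD) screening** on colour fundus photographs.

Screening pipelines for diabetic retinopathy, glaucoma, cataract, AMD,
hypertensive retinopathy and myopia all start from the same raw material: an
8-bit colour fundus photograph in which the informative circular retina sits
on a large, nearly black camera background, and end at the same place: a
patient-level 8-bit label vector in the order
**(Normal, DR, Glaucoma, Cataract, AMD, Hypertension, Myopia, Others)**.
`fundoprep` implements the stages between the two — for pipeline developers
who need each stage reusable, testable and reproducible without a clinical
dataset in hand:

- **Region-of-interest cropping.** A gradient circular Hough transform
  locates the fundus disc (Sobel edge pixels vote for centres along their
  gradient direction over radii in `[⌊min(H,W)/4⌋, max(H,W)]`; accumulator
  threshold 30, edge threshold 50, centres ≥ 20 px apart). Among the ranked
  circle candidates, the chosen one is the first whose bounding box —
  expanded by 5 rows/columns — contains every non-zero pixel, so only
  background is cropped away. An Otsu largest-contour crop is included as
  the classical baseline, and a tight non-zero bounding box as fallback.
- **Enhancement operators.** Green-channel extraction; CLAHE, the per-tile
  clipped equalization `I_eq = ⌊(L−1) Σ_{n=0}^{M_ij} P_n⌋` with clip limit 2
  on a 5×5 tile grid; the Gaussian unsharp blend
  `I_gs = α·I + β·(G_σ ∗ I) + γ` with `α = 4, β = −4, σ = 10, γ = 128`;
  and multiscale retinex
  `I_msr = Σ_n W_n (log I − log(G_{σ_n} ∗ I))` with scales `(5, 35, 150)`
  and equal weights.
- **Vessel operations.** Pluggable segmentation backends (a classical
  CLAHE + black-tophat stand-in ships in the box), mask cleanup — zero
  intensities below 20, then zero connected components under 100 px — and
  diffusion-based vessel inpainting.
- **Labels.** Keyword-to-label relabelling of ODIR-style manifests with
  union verification (Normal kept only when *both* eyes read
  `normal fundus`), label-wise-maximum two-eye aggregation, and DDR
  normal/abnormal binarization (grade 0 vs 1–4; grade 5 excluded).
- **Augmentation.** Seeded horizontal/vertical flips plus uniform
  random-angle rotation (±30° default), a 4× batch expansion.
- **Evaluation.** Macro precision/recall (Σ TP_c/(TP_c+FP_c) averaged over
  the C = 8 classes), F1 as their harmonic mean, the unweighted mean of
  per-label Cohen's kappa `(P_o − P_e)/(1 − P_e)`, macro ROC AUC, a
  per-decision challenge score, and 2-of-3 majority-rule ensembling.
- **Models.** Exact layer-by-layer trainable-parameter accounting for eleven
  ImageNet backbones with the final layer replaced by an 8-way head, the
  multi-label one-versus-all max-entropy loss, and a desk-scale trainable
  head for end-to-end smoke training on a CPU.
- **Explanation.** Grad-CAM maps from supplied activations/gradients,
  thresholded at 100 into masks, drawn as green (score ≥ 0.5) or red
  contours.
- **Synthetic data.** A seedable fundus generator (bright, possibly clipped
  disc on a < 20-intensity background, branching vessels, per-disease lesion
  stamps) with exact ground truth — disc circle, vessel mask, lesion
  coordinates, label vector — so the whole pipeline is testable end to end.

## Worked example

```r
library(fundoprep)

spec <- synth_spec(seed = 42, disc_center = c(127.5, 127.5), disc_radius = 100,
                   lesion_counts = list(exudate = 4, hemorrhage = 3))
fundus <- generate_fundus(spec)
fundus
#> synthetic fundus 256x256, disc r=100 at (128, 128), label 01000000

roi <- crop_roi(fundus$image, hough_params(nonzero_threshold = 19))
roi$box
#> crop box rows [27, 229), cols [27, 229), method=hough

enhanced <- clahe(extract_channel(roi$image, "G"))
mask <- clean_mask(segment_vessels(roi$image))
mask
#> vessel mask 256x256, 5552 non-zero px, 8-connectivity

model <- build_classifier(model_spec("ResNeXt50"))
model
#> ResNeXt50 classifier: 8-way head on d=2048, 22,996,296 trainable parameters

u <- union_and_verify(keywords_to_label("moderate non proliferative retinopathy"),
                      keywords_to_label("normal fundus"),
                      declared = "01000000")
u$label
#> 01000000 (D)
u$verified
#> [1] TRUE
```

The exudate/haemorrhage lesions make this a diabetic-retinopathy image, so
the generator labels it `01000000`. The Hough crop finds the disc's bounding
square (the true disc spans rows/cols 28–228; `nonzero_threshold = 19` tells
the selector that anything at 19 or below is camera background). The
detected circle box, green-channel CLAHE image and cleaned vessel mask are
the inputs the classification stage consumes, and the keyword union
reproduces the declared patient label: with one diseased and one normal eye
the Normal finding is dropped.

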