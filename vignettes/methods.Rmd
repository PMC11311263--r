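---
title: "Hybrid microcalcification detection: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid microcalcification detection: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microcalcifications (MCs) are calcium deposits of roughly 0.1–1 mm that
appear in mammograms as small bright spots. Clustered, linear, or segmental
arrangements are early markers of malignancy, but at full-field digital
mammography resolution (~0.07 mm/px) a deposit spans only about 1.4–14
pixels and is easily confounded with parenchymal texture. `mammocalc`
implements a hybrid detection-and-localization pipeline: classical
descriptive filters summarize edges and texture, a small convolutional
network classifies whole images as MC-positive or MC-negative, and grayscale
morphology pinpoints candidate deposits in positive images.

## The synthetic phantom: what it emulates, and what it does not

Every stage is exercised on phantoms from `generate_phantom()`, because
clinical mammogram collections cannot ship inside a package and public
databases require accession. A phantom consists of:

* a **half-elliptical breast foreground** flush with the left or right image
  edge (the silhouette of a CC/MLO view), on an exact-zero background;
* **parenchymal texture**: Gaussian white noise low-pass filtered to a
  correlation length of `tissue_texture_scale` pixels (default 24 px ≈ 1.7 mm
  at the default 0.07 mm/px spacing), scaled to ±0.08 of the dynamic range
  around a mid-gray of 0.45. The default scale encodes the physical fact that
  parenchymal structure lives at millimetre scale — an order of magnitude
  above deposit scale — which is precisely why a top-hat transform with a
  sub-millimetre-tuned structuring element can isolate deposits at all;
* **deposits** as radially symmetric raised-cosine bumps whose peak sits
  `spot_contrast` above the local background. A raised cosine avoids the
  aliasing a hard disk would show at 1–14 px diameters. Diameters are drawn
  uniformly in `spot_diameter_range` (mm) and converted by the pixel
  spacing; centers follow one of five clinically named layouts (scattered,
  clustered, segmental, linear, regional), all parameterized by a single
  dispersion radius, the linear layout by a random chord with perpendicular
  jitter below 1.5 px;
* optional **annotation artifacts**: dashed bright blocks outside the breast,
  standing in for the equipment markings that preprocessing must remove.

What the phantom does **not** model: X-ray physics (quantum noise, scatter,
beam hardening), pectoral muscle, vasculature, skin folds, benign macro
calcifications, and the long-tailed intensity statistics of real detectors.
Passing the synthetic study therefore demonstrates that the pipeline's
machinery is correct and internally consistent — not that its operating
points transfer to clinical data. The phantom's exact ground truth
(`PhantomTruth`: spot centers, diameters, contrast, label) is what makes the
quantitative localization scoring possible; the equivalent clinical ground
truth would come from radiologist annotation.

## Preprocessing

Heterogeneous inputs are normalized in four steps, in this default order:

1. **Grayscale conversion** with the ITU-R BT.601 luminance weights
   0.2989/0.5870/0.1140 — many mammogram exports are "false RGB" with three
   near-identical channels. Intensities stay real-valued end to end;
   quantization (round-half-to-even) happens only when a file is written.
2. **Artifact removal**: 4-connected components of `{pixels > 0}` are
   labeled and everything but the largest-area island (the breast) is set to
   background. Ties go to the first component in raster order.
3. **Intensity windowing** (`voi_window()`): the linear center/width map used
   by DICOM VOI-LUTs. When no window is given, a fallback spans the 2nd–98th
   foreground percentiles; a constant image is returned unchanged.
4. **Bilinear resizing** to a standard square (default 1024), rescaling the
   physical pixel spacing per axis.

Whether windowing should precede or follow island removal is genuinely open;
removal-first is the default (a window computed on percentiles is more
stable once bright annotation marks are gone) and the order is a flag.
DICOM parsing is out of scope — no R DICOM reader is a package dependency —
so readers cover PNG and TIFF; windowing parameters from a DICOM header can
be passed explicitly.

## Augmentation and splitting

The geometric augmentations are scale factors {0.8, 1.0, 1.2} about the
image center on a fixed canvas (content scales, the CNN input shape does
not), exact right-angle rotations {90°, 180°, 270°} (pure pixel
permutations, counter-clockwise positive), and horizontal/vertical
reflections. Each transform is applied to the original independently — no
compositions — and the identity scale emits nothing, so a full default plan
turns each image into 8 (1 original + 2 scales + 3 rotations + 2
reflections). Whether transforms should compose is unknowable from the
published counts; independent application keeps the enumeration predictable.

`stratified_split()` partitions each class 70/20/10 with round-half-up on
train and validation and the remainder to test. This is the only rounding
convention that maps a 2748/2942 two-class cohort to 1924/550/274 and
2059/588/295; membership is a seeded shuffle sliced into blocks.

## The feature stack

Eight channels, always in this order:

| channels | filter | what it sees |
|---|---|---|
| 1–2 | Prewitt 3×3 pair | horizontal / vertical intensity gradients |
| 3–7 | Gabor 5×5 bank at 0°, 45°, 90°, 135°, 180° | oriented texture at deposit scale |
| 8 | windowed GLCM contrast | local second-order texture roughness |

The 2 + 5 + 1 composition is the only arithmetic by which the three filter
families yield the classifier's 8 input channels. All filtering is
**cross-correlation** (kernel unflipped) with zero-padded same-size output;
the border ring where padding enters carries a `valid = FALSE` flag. Note
one consequence tested explicitly: the response to an impulse is the
point-reflected kernel, as it must be under correlation.

The five **canonical Gabor matrices** are fixed numeric fixtures (peak
coefficient 0.7726 at 0°). They are intentionally not regenerated from the
Gabor closed form: no single (σ, γ, ψ) reproduces them — the 0° matrix is
radially symmetric and the 180° matrix differs from the 0° one, which the
closed form cannot produce — so the printed bank is treated as authoritative
and shipped verbatim, with a `parametric` mode (λ = 1/0.625, configurable
envelope) provided for exploration and clearly documented as approximate.

The **GLCM channel** has no published windowing recipe, so the package picks
one and exposes every knob: window 17 px, stride 8, 8 gray levels (uniform
binning over the window's min–max), distance 1, counts pooled over the four
offsets (0°, 45°, 90°, 135°), Haralick *contrast* as the default feature,
bilinear upsampling of the coarse grid back to image size. Contrast is the
default because deposits are precisely local high-contrast events;
correlation, energy, and homogeneity are selectable.

Each channel is min–max normalized to [0, 1] (a constant channel maps to 0)
and bilinearly resampled to the classifier side — 508 for the full-scale
geometry, pairing a 1024² image with the 508×508×8 input.

## The convolutional classifier

The default architecture is two blocks of 16 unpadded 3×3 convolutions with
ReLU and 2×2 max-pooling (floor division), then flatten, a 64-unit ReLU
dense layer, and one sigmoid output:

508×508×8 → conv 506×506×16 → pool 253 → conv 251 → pool 125 → flatten
250,000 → dense 64 → sigmoid.

2×2 floor pooling is the only pooling consistent with 506→253 and 251→125;
a third block is one config entry away. The dense width (64) and He-normal
seeded initialization are package choices — the reference architecture
leaves them open. An image is called positive when the sigmoid output
strictly exceeds the threshold (default 0.5); an exact tie is negative.

Training is minibatch Adam on binary cross-entropy with an L2 weight
penalty (`loss + l2·Σw²`) and inverted dropout on the dense activations,
active in training only. The tuned full-scale recipe (learning rate 1e-6,
batch 8, 80 epochs, dropout 0.2, L2 0.01) is the `train_config()` default;
published variants of the learning rate (5e-7 initial table, 5e-6 pre-tune)
are selectable. The per-epoch history records train/validation loss and
accuracy, and the weights at the best validation loss are the ones retained.

The network is implemented in base R — im2col patch matrices driving BLAS
matrix products forward and backward — because the package targets exact,
single-threaded reproducibility: given the same seed, initialization, batch
order, and dropout masks are bit-identical, so training runs are too. At the
synthetic study sizes (48×48×8 stacks) a full train-and-evaluate cycle takes
well under a minute.

## Localization

`localize_pipeline()` implements the morphological route: grayscale opening
(erosion then dilation, borders by edge replication) with a disk structuring
element, white top-hat `I − (I ∘ B)`, thresholding, and 8-connected
candidate extraction (centroid, 0-based half-open bounding box, area, peak
response as score).

* **SE radius** defaults to `ceil(1.0 mm / spacing / 2) + 1` — just larger
  than the largest clinically relevant deposit radius, so every deposit up
  to 1 mm is removed by the opening and appears in the top-hat.
* **Threshold**: mean + 3·sd of the nonzero response values by default; an
  absolute threshold is selectable.
* **Skin-line masking**: the breast boundary is a step edge and rings under
  any top-hat, so the response is zeroed outside the foreground eroded by
  the SE radius before thresholding. This is standard practice in
  mammography CAD and is the one step added beyond the minimal transform
  chain (it can be disabled).
* 8-connectivity is used for candidate blobs, in contrast to the 4-connected
  breast-island detector: deposits are compact and diagonal adjacency should
  not split them.

A known limitation, measured and accepted: on *negative* phantoms the
adaptive mean+3σ rule keeps of the order of one to three low-scoring texture
blobs per image (median 2 at the study conditions). This is intrinsic —
threshold exceedance at 3σ is scale-invariant at roughly 10⁻³ of pixels, and
with ~(192/24)² independent texture patches some always cross — and no
texture amplitude changes it. Their scores sit far below deposit responses
(< 0.3 vs ≈ 0.6 at contrast 0.6), and in the end-to-end flow localization
runs only on classifier-positive images, which is the designed false-positive
gate. A distance-transform/watershed split for touching deposits was
considered and left out of the default path.

Localization is scored against phantom truth by greedy one-to-one matching
of candidate centroids to planted centers by ascending distance; the 3 px
match radius used in the acceptance study is a package convention (there is
no published quantitative localization criterion to adopt).

## Evaluation

`confusion()` / `metrics()` compute recall (sensitivity), specificity,
precision, accuracy, and F1 from the four counts. A metric with a zero
denominator is returned as `NA` and named in an `undefined` field — never
silently zero-filled. `roc_auc()` sweeps thresholds over the unique scores
and computes AUC by the rank (Mann–Whitney) statistic, which handles tied
scores by rank-averaging. `probability_distribution_export()` partitions
per-sample probabilities by confusion outcome for distributional inspection.

## The synthetic study and its problem sizes

The acceptance study (also what `scripts/acceptance.R` reruns) uses these
conditions, chosen once: 96×96 phantoms at 0.07 mm/px, 5 deposits of
0.3–1.0 mm at contrast 0.6 per positive, 48×48×8 stacks (GLCM window 9,
stride 8), an 8-filter two-block network with a 32-unit dense layer, Adam at
learning rate 1e-3, batch 8, dropout 0.2, L2 1e-4, 20 epochs, 48 training /
16 validation images, 40 held-out test images; localization on 20 positive
192×192 phantoms with the default SE radius 9 and 3 px matching. The
learning rate is deliberately *not* the 1e-6 full-scale default: that value
is tuned to a multi-thousand-image clinical corpus, and at 64 samples a
standard Adam magnitude is the appropriate choice. Typical results: held-out
accuracy 92–98%, AUC 0.95–1.0, localization recall 97–99%.

## Numerical conventions

* Coordinates are 0-based in serialized output, row-major, origin top-left;
  in-memory R objects use native 1-based indexing. Bounding boxes are
  half-open.
* Images are real-valued matrices with a tracked display range; file writers
  quantize to 8-bit PNG or 16-bit TIFF at the last moment.
* Degenerate inputs have defined behavior throughout: constant images pass
  windowing unchanged, constant channels normalize to 0, a constant GLCM
  window lands in one bin with correlation defined as 0, empty candidate
  lists and zero-denominator metrics are flagged rather than invented.
* All randomness flows through explicit seeds (phantom specs, split,
  initialization, training); the RNG state of the calling session is saved
  and restored around every seeded operation.
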