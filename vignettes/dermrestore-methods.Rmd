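---
title: "Restoring hair-occluded and noisy dermoscopic images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring hair-occluded and noisy dermoscopic images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermrestore)
```

## The problem

Dermoscopic images of skin lesions are routinely degraded by two artifact
families: dark curvilinear hair strands that occlude the lesion, and additive
sensor noise from poor illumination during acquisition. Both corrupt exactly
the pixels a downstream lesion classifier depends on. `dermrestore`
implements the two restoration pipelines — morphological hair removal with
fast-marching inpainting, and non-local means denoising — together with a
seeded synthetic corpus generator and a small transfer-learning harness, so
the whole claim "artifact removal improves classification" can be exercised
end to end on synthetic data, offline, on one CPU.

## Hair removal

`dehairInpainted()` runs five stages at native resolution:

1. **Gaussian blur** (3×3) then **median blur** (3×3). Both use reflect
   padding. The Gaussian σ is derived from the kernel size as
   `0.3·((k−1)·0.5 − 1) + 0.8` when not given; no single value is canonical
   for this recipe, and the derive-from-size rule keeps the kernel sensible
   at any odd size.
2. **Grayscale** conversion with Rec. 601 luma weights
   (0.299, 0.587, 0.114), the dominant convention for consumer-camera
   imagery.
3. **Blackhat** under an 11×11 cross structuring element: morphological
   closing (dilate, then erode) minus the input. The closing fills dark
   structures thinner than the cross arms, so the residue is a non-negative
   response concentrated on hair-width dark curves and near-zero on the
   (comparatively wide) lesion.
4. **Threshold** at 10 (strict `>`, ties excluded) on the 0–255 response.
   Ten is low enough to catch faint thin hairs and high enough that the flat
   response off-hair (zero for locally constant skin) stays out of the mask.
   It is exposed in `dehairConfig()` because darker skin tones or weak hairs
   may warrant other settings.
5. **Fast-marching inpainting** of the masked region of the median-blurred
   image, radius ε = 1.

### The inpainting model

Let Ω be the masked region and ∂Ωi the known pixels 4-adjacent to it. A
distance field T solves the discrete eikonal equation |∇T| = 1 with T = 0 on
∂Ωi, computed by fast marching with the standard quadratic upwind update
(`eikonalUpdate()`): from the smallest usable horizontal value t_h and
vertical value t_v, T = (t_h + t_v + √(2 − (t_h − t_v)²))/2, degenerating to
min + 1 when the two differ by ≥ 1. Outside Ω the analogous distance is
computed and negated, giving a signed field.

Masked pixels are then filled in non-decreasing (T, row, col) order — ties
broken lexicographically so runs are deterministic — and each estimate is

I(p) = Σ_q w(p,q)·[I(q) + ∇I(q)·(p−q)] / Σ_q w(p,q),

with q ranging over the known pixels in the Chebyshev ε-ball of p (ε = 1:
the 8-neighbourhood). The weight is the product of three components:
alignment of p−q with the advancing-front normal (the normalised gradient of
T at p, floored at 1e−6 so weights stay positive when the gradient
degenerates), inverse squared distance (scale d0 = 1 px), and closeness in
boundary distance (scale T0 = 1 px). Image gradients ∇I(q) use central
differences over known pixels only, one-sided at known/unknown interfaces,
zero for isolated pixels. Freshly inpainted pixels become known for later
ones. The estimate reproduces constants exactly (the weights normalise) and
first-order ramps up to discretisation error; off-mask pixels are returned
bit-identical.

Because the literal pipeline inpaints the *blurred* image, the default
restored output is globally softened. `dehairConfig(inpaintSource =
"original")` instead transplants only the on-mask inpainted values into the
unblurred input; the blurred variant remains the default because it is the
pipeline as specified, and the softening is part of what the downstream
experiment measures. A `maskDilate` option exists for 1-px hair halos and is
off by default (the threshold mask is applied as is).

## Denoising

`denoiseImage()` applies non-local means in CIELAB. The image is converted
(sRGB transfer curve, D65 white — the consumer-camera convention; the
package's conversion round-trips within ±1 intensity level in gamut), the
channels are rescaled to the 0–255 convention (L × 2.55, a and b shifted by
+128) so the filter strengths keep their usual meaning, and L is denoised
with `h` while a and b are each denoised with `hColor`; both default to 10,
the conventional strength for this material. Chroma channels are filtered
separately rather than with a joint two-channel patch distance; separate
filtering keeps every channel's behaviour identical to the grayscale
operator that the brute-force oracle checks.

For a pixel i, every pixel j in the 21×21 search window (radius 10; patches
7×7, radius 3) contributes weight

w(i,j) ∝ exp(−max(d(i,j) − 2σ², 0) / h²),

where d is the mean squared difference of the two reflect-padded patches and
σ is estimated from the channel by the high-pass/MAD estimator
(`estimateNoiseSigma()`): the 3×3 operator [1 −2 1; −2 4 −2; 1 −2 1]
annihilates constant and linear structure, and the median absolute deviation
of its interior response, divided by 0.6745·6, is a robust σ in intensity
units. The 2σ² offset removes the patch distance contributed by the noise
itself, so genuinely similar patches average at full strength. Weights are
normalised to sum to 1; the self-weight is set to the maximum of the other
weights in the window (the standard stabilisation; the literal exp(0) = 1
mode is available and mirrored by the test oracle). Windowed summation is
the default; a `fullImage` flag honours the literal whole-image average on
small inputs. The implementation enumerates displacement offsets and
box-filters squared-difference images, which is algebraically the per-pixel
definition; the test suite holds it to the direct-definition oracle within
1e−6.

## The synthetic corpus

Real seven-class dermoscopy corpora cannot ship with a package, so
`generateLesionPhantom()` builds stand-ins: a skin-toned background, smooth
low-frequency texture (a coarse Gaussian grid, bilinearly upsampled,
amplitude 6 intensity levels by default), and a soft-edged ellipse whose
color and size family is fixed per class. The seven families are
dermoscopy-plausible (browns, near-black, red, blue-gray, tan, pink, violet)
and separated widely enough that a nearest-centroid classifier on mean
lesion color alone is nearly perfect — deliberate, so the harness has signal
whose degradation under occlusion is measurable.

`drawProceduralHairs()` rasterises quadratic Bézier strokes with per-hair
thickness 1–4 px and dark brownish intensity 10–90, re-drawing strokes that
would touch an existing one so the truth mask has one component per strand.
Corruption is hard replacement, exactly localised to the mask.
`addGaussianNoise()` adds i.i.d. zero-mean noise per pixel per channel in
floating point and clips to [0, 255]; the dermoscopic regime of interest is
σ from 1 to 30, and σ is drawn uniformly from that range when not fixed.
Statistical calibration tests use mid-gray constants so clipping cannot bias
the empirical σ. Every generator is a pure function of its seed; corpora
written by `generateCorpus()` regenerate byte-identically.

What the phantoms do *not* emulate: real lesion morphology (asymmetry,
pigment networks, globules), specular highlights, rulers, ink marks, vignettes,
and the class imbalance of clinical corpora. Passing tests therefore show
the pipelines behave as specified and that the *direction* of artifact
effects reproduces; they do not certify clinical-grade accuracy numbers.

## The classification harness

The harness follows the transfer-learning scheme: a frozen feature
extractor, and a single new fully connected layer with softmax for the seven
classes, trained with Adam (learning rate 1e−3, β1 = 0.9, β2 = 0.999,
ε = 1e−8), categorical cross-entropy, shuffled minibatches of 32, 25 epochs,
and an 80/20 stratified split (we stratify; it makes small-corpus
replicates comparable). TAcc/TLoss/VAcc/VLoss are recorded every epoch; the
20% held-out share doubles as the validation set, keeping the VAcc/VLoss
naming.

Pretrained ImageNet backbones are deliberately not bundled — they are the
one ingredient that cannot be rebuilt from a seed — so the
`BackboneAdapter` contract accepts any feature function and the package
ships `tinyCnnBackbone()`: three blocks of 3×3 convolution, ReLU, and 2×2
average pooling (widths 8/16/32), fixed He-initialised random weights,
global average pooling to 32 features. Random frozen convolutional features
preserve the color/scale statistics that separate the phantom classes, which
is all the scaled-down experiment needs. Features are z-scored on the
training split before the head (a conditioning aid; optional). No
augmentation, schedule, or early stopping is used. Training aborts with a
diagnostic on non-finite loss.

`runExperiment()` applies the identical backbone, initialisation, split and
minibatch schedule to each corpus variant (clean / corrupted / restored of
the same underlying images), so metric differences are attributable to the
pixels alone; across replicate seeds the direction of an effect is read as
the fraction of seeds in which one variant's final VAcc is at least the
other's.

## Problem sizes and numerical choices

The documented study conditions, used by the test suite and
`scripts/acceptance.R`, are: 64×64 phantoms, 20 per class (140 images),
heavy hair occlusion (15–25 strands per image), noise at σ = 20, five
replicate seeds, and the training hyperparameters above. Restoration
quality is summarised by mean absolute error against the clean phantom
(whole image) and Dice overlap between detected and true hair masks.

Numerical conventions, fixed package-wide so oracles and implementation
agree: reflect (symmetric, edge-included) padding for every filter,
morphology operator and patch lookup; strict inequality at the binary
threshold; 0-based pixel geometry with row 0 at top (R-facing interfaces
are 1-based); interior arithmetic in doubles with quantisation only at file
boundaries; PNG as the lossless interchange format (u8 round trips
bit-exactly); priority ties in the fast-marching band broken by (T, row,
col); the inpainting weight floor 1e−6; predicted-class ties broken toward
the lowest class index.

Degenerate inputs are contracts, not surprises: an all-true inpainting mask
is an error (nothing known to propagate from), an empty mask is the
identity, sigma 0 noise is the identity, a corpus with an empty class
refuses to split, and corpus processing logs failures and continues
deterministically.

## Known limitations

- The hair detector responds to any dark thin structure; pigment-network
  lines of real lesions can enter the mask (on phantoms, only hairs exist).
- Dehairing inherits the pipeline's blur; quantitative MAE gains mix
  "hair removed" with "image softened". The `original` source mode isolates
  the former.
- NL-means assumes stationary additive noise; σ estimation is per channel
  and global.
- The tiny backbone is a stand-in for pretrained networks; absolute
  accuracies on small phantom corpora say nothing about full-scale numbers,
  only the relative ordering of clean/corrupted/restored variants is
  meaningful.
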