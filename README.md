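# dermrestore

Restoration of dermoscopic skin-lesion images corrupted by **hair strands**
and **sensor noise**, plus the tooling to measure what restoration buys a
downstream lesion classifier. Intended for researchers building or
evaluating computer-aided diagnosis pipelines on dermoscopy who need the
classical restoration stages as reproducible, testable components rather
than opaque library calls.

## What it implements

**Hair removal** (`dehairInpainted`): Gaussian blur (3×3) → median blur
(3×3) → grayscale → blackhat under an 11×11 cross structuring element →
binary threshold (default 10) → fast-marching inpainting of the detected
mask. The inpainting fills the masked region Ω from its boundary inward in
order of the eikonal distance T (|∇T| = 1, T = 0 on ∂Ωi), estimating each
pixel as

> I(p) = Σ\_{q ∈ B\_ε(p)} w(p,q) [ I(q) + ∇I(q)·(p−q) ] / Σ w(p,q)

with w(p,q) the product of directional, geometric-distance and
level-set-distance components (scales d0 = T0 = 1 px, ε = 1).

**Noise removal** (`denoiseImage`): non-local means in CIELAB, luminance and
chroma filtered separately with strengths h = hColor = 10, 7×7 patches in a
21×21 search window, weights exp(−max(d − 2σ̂², 0)/h²) normalised per
pixel,

> NL[v](i) = Σ\_j w(i,j) v(j).

**Synthetic corpus** (`generateLesionPhantom`, `drawProceduralHairs`,
`addGaussianNoise`, `generateCorpus`): seven-class lesion phantoms,
Bézier-stroke hair occlusion with ground-truth masks, zero-mean Gaussian
noise with σ ∈ [1, 30] — every generator a pure function of its seed.

**Classification harness** (`tinyCnnBackbone`, `attachHead`, `trainHead`,
`runExperiment`): frozen feature extractor + trainable 7-class softmax head,
Adam at 1e−3, batch 32, 25 epochs, categorical cross-entropy, stratified
80/20 split, TAcc/TLoss/VAcc/VLoss per epoch.

## Worked example

```r
library(dermrestore)

# a clean class-0 phantom, heavily occluded by 18 procedural hairs
ph   <- generateLesionPhantom(0, size = 64, seed = 101)$image
pair <- drawProceduralHairs(ph, hairParams(nHairs = 18, seed = 202))

out <- dehairInpainted(pair$corrupted)
cat("mask area:", round(mean(pixelValues(out$mask)), 3), "\n")
cat("Dice vs truth:", round(diceCoefficient(out$mask, pair$truthMask), 3), "\n")
cat("MAE hairy:   ", round(mean(abs(pixelValues(pair$corrupted) - pixelValues(ph))), 2), "\n")
cat("MAE restored:", round(mean(abs(pixelValues(out$restored) - pixelValues(ph))), 2), "\n")
```

```
mask area: 0.333
Dice vs truth: 0.724
MAE hairy:    22.02
MAE restored: 7.22
```

About 20% of the pixels were truly occluded; the detected mask is somewhat
wider (33%) because the blackhat halo around each strand crosses the
threshold too. Dehairing recovers most of the occluded intensity — the mean
absolute error against the clean phantom drops from ~22 to ~7 intensity
levels, the residual being dominated by the pipeline's own blur.

The same comparison for noise:

```r
noisy <- addGaussianNoise(ph, sigma = 20, seed = 303)
den   <- denoiseImage(noisy)
cat("MAE noisy:   ", round(mean(abs(pixelValues(noisy) - pixelValues(ph))), 2), "\n")
cat("MAE denoised:", round(mean(abs(pixelValues(den) - pixelValues(ph))), 2), "\n")
```

```
MAE noisy:    15.92
MAE denoised: 2.67
```

A command-line front end over the same functions is installed at
`inst/scripts/dermrestore` (subcommands `dehair`, `denoise`, `simulate`,
`process`).

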