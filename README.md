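# dtcwtseg

Segmentation of 2-D brain-tumor image slices built around the dual-tree
complex wavelet transform (DTCWT), with an optional reinforcement-learning
refinement stage. The package is aimed at researchers who need a fully
scripted, reproducible pipeline from a noisy grayscale slice to a labelled
mask — plus the synthetic phantoms and evaluation metrics to validate every
stage without access to clinical data.

## What it does

The pipeline has four computational stages:

1. **Denoising.** The image is decomposed by a 2-D DTCWT (Kingsbury
   near-symmetric 13,19-tap level-1 filters, Q-shift 14-tap beyond; six
   complex directional subbands per level). Each detail coefficient
   β₁ is paired with its parent β₂ at the next coarser scale and shrunk by
   the bivariate MAP rule

   α̂₁ = (√(β₁²+β₂²) − √3 σₙ²/σ)₊ / √(β₁²+β₂²) · β₁,

   the closed-form posterior mode under a Gaussian noise model (SD σₙ,
   estimated by a median absolute deviation rule on the finest diagonal
   subbands) and a circularly symmetric bivariate Laplacian-type prior with
   local signal scale σ. The factor is applied to real and imaginary parts
   alike, so phase is preserved. Reconstruction is followed by a few
   iterations of Perona–Malik anisotropic diffusion
   ∂I/∂t = div(c(‖∇I‖)∇I) with c(g) = exp(−(g/κ)²).
2. **Features and clustering.** Per-pixel feature vectors collect the
   smoothed, square-rooted subband magnitudes of all 6·levels orientations
   plus the lowpass intensity; k-means (k-means++ seeding, Lloyd
   iterations) groups pixels into feature classes with per-class energies
   V(uᵢ) = Σ‖xᵢ‖².
3. **MAP segmentation.** Labels minimize the sum of a characteristic
   (data) energy — per-class diagonal-Gaussian negative log likelihood
   minus log prior — and a marker (smoothness) energy — β times the number
   of disagreeing 4-neighbour pairs (a Potts prior). Minimization is by
   iterated conditional modes (ICM): deterministic raster sweeps whose
   total energy never increases.
4. **RL refinement.** A small agent walks superpixel focus regions and
   chooses discrete mask edits (dilate/erode a class by one pixel inside
   the region, relabel the region, or STOP). It is trained with the
   clipped-surrogate policy objective −min(rₜkₜ, clip(rₜ, 1±σ)kₜ), a ½(V−R)²
   value loss, an entropy regularizer, and generalized advantage
   estimation, with per-step rewards equal to the change in macro
   F-measure against ground truth.

Evaluation metrics: pair-consistency similarity index (Rand index over
pixel pairs), an information-loss index (variation of information
normalized by log N), mean symmetric boundary distance normalized by the
image diagonal, and pixel-level F-measure — each backed by a brute-force
oracle in the test suite.

## Worked example

```r
library(dtcwtseg)

# a 128x128 brain-like phantom: skull ring, tissue, one tumour blob
spec  <- phantom_spec(128, 128, n_classes = 4, tumor_count_range = c(1, 1),
                      seed = 7)
ph    <- generate_phantom(spec)
noisy <- add_noise(ph$image, sigma = 0.1, seed = 42)

den <- denoise_image(noisy, levels = 4)
psnr(noisy, ph$image)   # 19.93 dB
psnr(den,   ph$image)   # 31.27 dB  (+11.3 dB from shrinkage + diffusion)

# supervised Gaussian/Potts fit on the wavelet features, then ICM
feats <- extract_features(dtcwt_forward(den, levels = 1))
model <- fit_segmentation_model(feats, ph$truth, beta = 2)
mask  <- match_labels(segment_icm(feats, model, max_sweeps = 10), ph$truth)

missegmentation_rate(mask, ph$truth)   # 0.037  (3.7% of pixels)
similarity_index(ph$truth, mask)       # 0.96
f_measure_macro(ph$truth, mask)        # 0.93
```

`psnr()` values are decibels against the known clean phantom; the
mis-segmentation rate is the fraction of disagreeing pixels after optimal
label alignment; the similarity index is the fraction of pixel pairs whose
same-class/different-class relation agrees with the truth.

A command-line interface over the same functions ships in
`inst/cli/dtcwtseg-cli.R` with subcommands `synth`, `denoise`, `segment`,
`refine-train`, `refine-apply`, `evaluate` and `run`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/dtcwtseg-cli.R", package = "dtcwtseg"))')
Rscript $CLI synth --n 4 --height 128 --width 128 --sigma 0.1 --seed 3 --out data/
Rscript $CLI denoise --in data/noisy_0001.tiff --out data/den.tiff --levels 4
Rscript $CLI segment --in data/den.tiff --out-mask data/mask.png --classes 4
Rscript $CLI evaluate --pred data/mask.png --truth data/truth_0001.png
```

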