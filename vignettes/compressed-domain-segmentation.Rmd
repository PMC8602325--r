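---
title: "Compressed-domain whole-slide segmentation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed-domain whole-slide segmentation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveseg)
```

## The problem and the pipeline

Whole-slide images (WSIs) of H&E-stained biopsies are gigapixel objects; a
segmentation model can only ingest modest windows of them, and the usual
escapes — decimating the image or shrinking the window — discard
high-frequency texture or spatial context that pathologists rely on. waveseg
implements the alternative this package is built around: run the model in a
*compressed domain* and undo the compression only at the very end, when the
per-window predictions are fused back into a slide-level probability map.

The stages for one slide:

1. **Tiling.** Overlapping sliding-window tiles (default 1024 px side,
   256 px stride). Overlap is deliberate: when tile predictions are summed
   back onto the slide, each pixel is averaged over every window that saw it,
   which both smooths seams and lets neighbouring context vote.
2. **Channel (z-axis) compression.** Otsu's threshold on BT.601 luminance
   separates near-white background from tissue. Over tissue pixels, the red
   and blue values are projected onto the first principal component of their
   2×2 covariance — in H&E, R and B carry the eosin/hematoxylin contrast
   while G is largely redundant with them — then min–max rescaled to [0, 1].
   Non-tissue pixels become 0. A grayscale conversion is available as the
   comparison compression (`gray_dwt_*` methods).
3. **Spatial (x/y) compression.** A single-level 2-D Haar DWT turns each
   compressed tile into four half-resolution sub-bands: the approximation LL
   and the vertical/horizontal/diagonal details LH, HL, HH.
4. **Prediction.** One probability predictor per sub-band (four independent
   models in production; see "Predictors" below).
5. **Reassembly.** Per-band tile maps are overlap-averaged into four
   slide-level half-resolution maps.
6. **Fusion.** Either the *wavelet-weighted ensemble* (WWE) — the package's
   core — or the scalar *weighted-average ensemble* (WAE) comparator.

## The wavelet-weighted ensemble

Let $Y = (Y_{LL}, Y_{LH}, Y_{HL}, Y_{HH})$ be the Haar sub-bands of the
binary tissue mask and $R_b$ the predicted probability map for band $b$. WWE
builds per-pixel weight maps

$$m_b = W_b\,(Y_b + \varepsilon),$$

multiplies each $R_b$ elementwise by $m_b$, and applies the inverse DWT:

$$R_{WWE} = \mathrm{IDWT}\big(m_{LL}\odot R_{LL},\; m_{LH}\odot R_{LH},\;
m_{HL}\odot R_{HL},\; m_{HH}\odot R_{HH}\big).$$

Under the normalization used here (below), $Y_{LL}$ is 1 inside tissue and 0
in background, and the detail bands of the mask are nonzero only along
tissue boundaries. So the weight maps concentrate ensemble mass on tissue,
keep detail-band influence near edges where it is informative, and reduce it
to the small offset $\varepsilon$ elsewhere — which is exactly where
detail-band predictions are noisiest. WAE, by contrast, applies one scalar
weight per band to the whole slide:
$R_{WAE} = \sum_b W_b R_b / \sum_b W_b$, computed at half resolution and
replicated 2× for scoring.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `w1..w4` | 2.1, 1.8, 1.8, 3.0 | scalar band weights (LL, LH, HL, HH) |
| `epsilon` | 0.1 | offset removing zero terms in the weight maps |
| `tile_size` | 1024 px (compressed) | sliding-window side |
| `stride` | 256 px | window step, both axes |
| threshold sweep | 0.1–0.9 step 0.1 | binarization operating points |
| grid | 0.3–3.0 step 0.3 | candidate values per weight in `wwe_fit()` |

The default weights are the grid-search optimum of the reference
configuration; `wwe_fit()` re-estimates them for any cohort by exhaustively
scoring all `grid^4` combinations on mean Dice (threshold 0.5 — the central
operating point; the sweep is reported alongside). Ties are broken toward the
lexicographically smallest `(w1, w2, w3, w4)` and the candidate iteration
order is fixed, so the fit is reproducible. The search exploits that
$R_{WWE}$ is linear in each $W_b$: four per-band contribution images are
precomputed per slide and each candidate costs four scaled additions rather
than a wavelet transform.

### Normalization of the Haar transform

Textbook presentations of the 2-D DWT often carry a global
$1/\sqrt{MN}$ factor, under which sub-band magnitudes depend on the image
size. waveseg instead defaults to the *mean-normalized* level-1 convention
(`ll` is the 2×2 block mean) because it is the one under which the WWE
weight semantics are interpretable: a binary mask yields weight maps in
[0, 1] before scaling, constant probability images are fixed points of `ll`,
and the `ll` band of a [0, 1] image stays in [0, 1]. The orthonormal
(energy-preserving) convention is available via `convention =
"orthonormal"`; perfect reconstruction holds under both, and the round trip
is tested to below 1e-9.

### Clipping

The raw WWE reconstruction can exceed [0, 1] — inside tissue the LL weight
is $W_1(1 + \varepsilon) = 2.31$ at the defaults — while downstream
consumers expect probabilities. The output is therefore clipped to [0, 1];
`clip = FALSE` retains the raw field for exact-math work. For binarization
at any threshold in (0, 1), clipping is a no-op, so the weight search can
skip it.

## Predictors

The sub-band models themselves (U-Net-family CNNs in production) are out of
scope: the package defines the predictor *contract* and ships two
desk-scale reference implementations plus an adapter.

- **oracle** — returns the training target derived from ground truth, plus
  optional clamped Gaussian noise. The target for every sub-band predictor
  is the half-resolution 2×2 majority-vote downsampling of the mask (ties
  to tumor). Sub-band models are treated as emitting *probabilities*, and
  the half-resolution mask is the natural probability-valued target shared
  by all four bands; the alternative — regressing the signed sub-band
  coefficients of the mask — would not be a probability and is not what the
  fusion stage expects.
- **classical** — a training-free logistic transform of box-smoothed
  intensity; useful as a weak but honest baseline.
- **external** — a function adapter for plugging in a real model
  (exchanging float32 TIFF tiles on disk if desired).

`dicece_loss()` implements the DiceCE training criterion — soft Dice plus
mean binary cross-entropy, equally weighted, smoothing 1e-6, probabilities
clamped to [1e-7, 1-1e-7] — for use by external training code.

## The synthetic cohort

No public cohort accompanies the method, so the package generates
pseudo-H&E slides with exact ground truth (`generate_slide()`,
`generate_cohort()`). What the generator emulates, because the pipeline's
behaviour depends on it:

- near-white background (all channels ≥ 230) against darker stained tissue,
  so Otsu masking works as on real slides;
- a two-stain linear color model: pink stroma (R > G, B > G), blue-purple
  nuclei (B > R > G), and a red-blue correlation over tissue that exceeds
  red-green — the property that justifies dropping G and running PCA on
  (R, B);
- tumor regions whose texture differs from normal tissue purely in
  nucleus-speckle *frequency content*, varied by lesion class (TAH densest
  and highest-frequency, HYPERP smooth low-frequency blobs), since
  frequency content is what the DWT pipeline is sensitive to;
- exact mask/image registration, with geometry rasterized at half
  resolution and replicated 2×2 so annotation boundaries align with the
  wavelet blocks (DWT-aligned annotations). This makes the noise-free
  oracle chain exactly invertible, which the identity tests exploit.

What it does **not** emulate: scanner optics, stain batch variation,
pyramidal WSI levels, artifacts (folds, ink, bubbles), or any biological
realism beyond the color and frequency structure above. Passing tests on
synthetic slides therefore validate the *pipeline machinery* — transforms,
fusion, metrics, reproducibility — not clinical performance.

Default conditions: 2048×2048 canvas (desk-scale while still yielding a
5×5 sliding grid at the default tile/stride), three tumor regions, tumor
fraction constrained to [0.05, 0.25] of the canvas by radius rescaling.
Every generator is a pure function of `(params, seed)`.

## Numerical and design choices

- **Ragged edges.** Tiling logically pads right/bottom with white up to the
  next valid origin and crops after reassembly. White is background-like, so
  Otsu assigns padding to background. The choice is ours; any fixed
  convention would do.
- **Otsu convention.** 256 unit-width bins on [0, 255]; ties broken toward
  the lowest qualifying split; the returned threshold sits half a bin above
  the lower class so strict and non-strict comparisons agree on integers.
  Constant inputs are rejected as degenerate.
- **PCA fit scope.** Per tile (each tile's own tissue pixels), with the
  eigenvector oriented so blue-dominance maps high — PCA signs are
  arbitrary, and fixing one keeps nuclei consistently bright. Tiles whose
  tissue pixels are identical return a flagged constant rather than an
  error, so background-only tiles flow through. A per-slide fit would be a
  small variation; per-tile is the default because compression statistics
  then travel with the tile.
- **Binarization** uses `map >= t`. Slides with no positive pixels in
  either mask score 1.0 on Dice/Jaccard (perfect-empty convention,
  configurable), and reported spreads are sample standard deviations.
- **WAE scoring resolution.** WAE fuses at half resolution; its output is
  replicated 2× so every method is scored against the same full-resolution
  annotation.
- **Identity weighting.** `identity_weights = TRUE` sets
  $W = (1,1,1,1)$, $\varepsilon = 0$ and an all-ones tissue mask, under
  which the weight maps become (1, 0, 0, 0) per block and WWE fusion
  reduces exactly to pixel replication of the LL map. With noise-free
  oracle predictors the whole chain then reproduces the ground truth
  bit-exactly — the strongest end-to-end correctness check the pipeline
  admits.
- **Benchmark metric.** On the standard fusion benchmark (20 slides,
  noise-free LL oracle, detail-band noise 0.2), each slide's Dice is
  averaged over the full 0.1–0.9 threshold sweep. At the central threshold
  alone a noise-free LL oracle makes the scalar ensemble essentially
  unbeatable, and the sweep is where robustness to the operating point —
  the practical argument for per-pixel weighting — is visible. The per-0.5
  numbers are reported alongside, not hidden.
- **Problem sizes.** The test and acceptance workloads use 2048² slides
  for the identity chain (5 slides), 512² slides with 256-px tiles for the
  4-slide weight search (the full 10⁴-candidate grid) and the 20-slide
  benchmark, and 64–256² images for unit tests. These sizes exercise
  multi-tile overlap, padding, and all five lesion classes while keeping a
  full run in the minutes range on one CPU.

## Limitations

- The reference predictors are oracles and intensity heuristics; nothing
  here trains or evaluates a real CNN, and no clinical claim follows from
  synthetic results.
- Single-level Haar only; multi-level decompositions and other wavelet
  families are out of scope.
- The ensemble weights are fitted by exhaustive search, not learned
  end-to-end; the grid is coarse by design (10⁴ candidates).
- Pyramidal WSI containers (SVS) are not read directly; slides enter as
  plain PNG/TIFF arrays.
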