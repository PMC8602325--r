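# waveseg

Tumor segmentation of H&E whole-slide images (WSIs) in a
**wavelet-compressed domain**, for computational-pathology researchers who
need to run segmentation models on gigapixel slides without throwing away
high-frequency texture through decimation or tiny crops.

## The method

A slide is cut into overlapping sliding-window tiles (1024 px, stride 256).
Each tile is compressed twice before any model sees it:

- **channel (z) compression** — Otsu's threshold on luminance masks out the
  near-white background; over tissue pixels the (R, B) values are projected
  onto the first principal component of their 2×2 covariance (G is dropped:
  in H&E it is largely redundant with the red-blue eosin/hematoxylin
  contrast) and rescaled to [0, 1];
- **spatial (x/y) compression** — a single-level 2-D Haar DWT yields four
  half-resolution sub-bands LL, LH, HL, HH.

One probability predictor per sub-band produces tile maps, which are
overlap-averaged into four slide-level sub-band maps `R_b`. The
**wavelet-weighted ensemble** (WWE) fuses them back to full resolution with
per-pixel weights derived from the DWT of the binary tissue mask
`Y = DWT(mask)`:

    m_b   = W_b * (Y_b + eps)                      b in {LL, LH, HL, HH}
    R_WWE = IDWT(m_LL.R_LL, m_LH.R_LH, m_HL.R_HL, m_HH.R_HH)   (then clipped to [0,1])

so low-frequency evidence dominates inside tissue while detail bands speak
mainly near edges, where they are informative. The scalar band weights
`W_1..W_4` (defaults 2.1, 1.8, 1.8, 3.0 with `eps = 0.1`) are fitted by
exhaustive grid search on mean Dice (`wwe_fit()`, grid 0.3–3.0 step 0.3,
10^4 candidates). A scalar weighted-average ensemble (WAE),
`sum(W_b R_b) / sum(W_b)`, and three spatial-domain baselines (standard,
small-ROI, low-resolution) serve as comparators, all scored by per-pixel
Dice / accuracy / Jaccard over a threshold sweep.

Because no public cohort accompanies the method, the package includes a
synthetic pseudo-H&E generator (near-white background, pink stroma,
blue-purple nuclei with the characteristic strong R–B correlation, and
class-dependent tumor texture frequency) with exact ground-truth masks, so
the entire pipeline is testable end to end.

## Worked example

```r
library(waveseg)

cohort <- generate_cohort(4, slide_params(width = 512, height = 512), seed = 1)
cfg <- pipeline_config("pca_dwt_wwe", tile_size = 256, stride = 128,
                       noise_sd = c(LH = 0.2, HL = 0.2, HH = 0.2), seed = 1)
run <- run_pipeline(cohort, cfg)
print(run)
#> pipeline run (pca_dwt_wwe): 4 slides ok, 0 failed
#> mean Dice at threshold 0.5: 0.9960

fit <- wwe_fit(cohort, grid = c(0.3, 0.9, 1.5, 2.1, 3.0), config = cfg)
print(fit)
#> Coefficients (band weights):
#>  w1  w2  w3  w4
#> 1.5 0.3 0.3 0.3
#> epsilon: 0.10
#>
#> Mean Dice at threshold 0.50 over 4 slides: 1.0000

summary(fit)
#> Best mean Dice by LL weight (w1), maximized over w2..w4:
#>  weight best_dice
#>     0.3 0.6627411
#>     0.9 0.9997935
#>     1.5 1.0000000
#>     2.1 1.0000000
#>     3.0 1.0000000
#>
#> w1 saturation point (within 0.005 of optimum): 0.90
```

Read: four 512² synthetic slides go through the full compressed-domain
pipeline with oracle predictors whose detail bands carry Gaussian noise
(sd 0.2). The fused WWE maps score mean Dice 0.996 at threshold 0.5 under
the default weights. Refitting the weights on this cohort reaches Dice 1.0;
the marginal curve shows the characteristic behaviour of the LL weight —
steep gains at small `w1`, saturation once the low-frequency band dominates
(here from `w1 = 0.9` on). `plot(fit)` draws that curve;
`predict(fit, newdata)` fuses new slides with the fitted weights.

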