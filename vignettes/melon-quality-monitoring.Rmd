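---
title: "Monitoring muskmelon internal quality from external phenotype images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring muskmelon internal quality from external phenotype images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ripening netted muskmelon (*Cucumis melo*) changes on the outside as it
changes on the inside: the rind drifts from green towards yellow, surface
netting develops, and fruit geometry settles, while sugars (fructose,
glucose, sucrose, total sugar), total soluble solids (TSS), vitamin C and
rind pigments (chlorophyll *a*/*b*, carotenoids) move with maturity.
`melonpheno` implements a non-destructive monitoring pipeline that predicts
these nine internal traits from a single RGB image of the fruit on a
standardized blue backdrop:

1. **Segmentation.** The excess-blue colour index $2B - R - G$ (a
   blue-excess variant of the excess-green index $2G - R - B$) is computed
   per pixel and thresholded by Otsu's method. Because the backdrop is
   blue-dominant, the index is high on the backdrop and near zero on the
   fruit, so the fruit mask is the *complement* of the thresholded region
   (`polarity = "backdrop_high"`). Small components are removed, small
   background holes filled, a binary opening with a disk applied, and the
   largest component kept (one fruit per frame).
2. **Feature extraction.** 65 external parameters per image, in a fixed
   numbering: 45 colour statistics (mean, sample SD, median, range, CV of
   R, G, B, CIELAB L/a/b, HSV H/S/V over the fruit pixels only), 6
   gray-level co-occurrence (GLCM) texture statistics of the netting
   (contrast, dissimilarity, homogeneity, energy, correlation, ASM), and
   14 contour morphology descriptors (area, perimeter, bounding box,
   convex hull area, minimum-area rotated rectangle, fitted-ellipse axes,
   minimum enclosing circle, equivalent diameter, aspect ratio, extent,
   solidity).
3. **Screening.** Each parameter is tested against each trait by Pearson
   correlation; the two-sided $p$ comes from
   $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df and parameters with $p < 0.05$
   (raw, no multiplicity correction — deliberately, as a screening step
   whose false positives the forest can absorb) enter that trait's model.
   The $-\log_{10} p$ profile against parameter number, with the threshold
   line at $-\log_{10} 0.05 = 1.301$, is the visual summary.
4. **Modelling.** One random forest regression per trait (`ntree = 300`),
   with `mtry` tuned over $1..\min(100, p)$ by 10-fold cross-validation
   repeated 3 times on a seeded 2/3 training split of *fruits* (views of
   one fruit never straddle the split). Accuracy is reported as RMSE, MAE
   and two $R^2$ conventions (below). Permutation importance under the MSE
   criterion ranks the predictors, and a simplified model is refit on the
   top 10.

## The two R-squared conventions

The monitoring literature this package follows prints
$$R^2 = \frac{\sum_i (\hat y_i - \bar y)^2}{\sum_i (y_i - \bar y)^2},$$
the explained-over-total sum of squares. For predictors that are not
least-squares fits of the data this ratio is **not** bounded by 1 (e.g.
$y = (1,2,3)$, $\hat y = (1,2,4)$ gives 2.5). `metrics()` therefore
returns both `r2_paper` (the formula above, kept for comparability) and
`r2_conventional` $= 1 - SS_{res}/SS_{tot}$, and every internal threshold
in this package uses the bounded conventional form. The two coincide
exactly when $\hat y$ is an OLS fit, which the test suite checks to
1e-10.

## What the synthetic generator states, and why

No image set is deposited with the original study, so the package carries
a seeded generator whose defaults *are* the stated world of the
experiment:

* **Cohort geometry**: 134 fruits × 3 views = 402 images. (The source
  reports 134 fruits, "130 samples", and per-trait assay sizes of
  101–130; we keep 134 × 3 to match the 402 images and expose per-trait
  missingness only through the screening's complete-case handling.)
* **Trait envelopes**: each trait is generated inside its published
  min–max envelope (e.g. carotenoids 0.12–0.40 mg/100 g, TSS 5.8–18.5%),
  as `melon_traits()` records.
* **Latent structure**: a single ripeness $r \sim U(0.05, 0.95)$ per
  fruit drives everything. Traits follow
  $\text{min} + (\text{max}-\text{min})\,\ell(r) + \varepsilon$, with
  $\ell$ a logistic link rescaled to $\ell(0)=0,\ \ell(1)=1$ and steepness
  $k = 4$ — chosen once so the link is visibly nonlinear yet the
  noise-free hue–trait correlation stays above 0.99, which is what makes
  colour-parameter screening meaningfully testable. Gaussian noise is
  clipped to the envelope; the default "calibrated" scale sets each
  trait's generative signal fraction to $R^2 = 0.9$.
* **Scenes**: an ellipse-shaped fruit (exactly rasterized — this raster
  *is* the ground-truth mask) with base hue $110 - 60r$ degrees (green →
  yellow), procedural netting made by thresholding band-limited noise at
  quantile $1-\text{density}$, a blue-dominant backdrop, a scalar
  illumination gain, and Gaussian sensor noise (SD 2 by default).
  Netting brightens all three channels equally and the gain is
  multiplicative, so neither changes pixel hue except through 8-bit
  rounding — hue is a clean, construction-level signal carrier.
* **Raster size**: 256 × 256 px. The physical camera's 5616 × 3744
  frames are a hardware fact the synthetic world does not need; all
  morphology is reported in working-resolution pixels, with an optional
  `mm_per_px` conversion.

What a green test on this world establishes: that the chain
segmentation → features → screening → forest recovers injected,
envelope-respecting, monotone colour signal at the study's geometry and
that every analytic contract holds. What it does not establish: real-rind
reflectance, shadowing, netting anisotropy, camera colour response, or
the study's real-data accuracy values — those require the undeposited
images and are expressly out of scope.

## Tunable parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `polarity` | `backdrop_high` | — | blue backdrop scores high on $2B-R-G$; flag provided since the convention could be inverted for other rigs |
| `min_object_frac` / `min_hole_frac` | 0.005 / 0.001 | image fraction | speck/hole scales; no sizes are published, these are working-resolution engineering defaults |
| `opening_radius` | 5 | px | smooths the thresholded rim at the working resolution |
| GLCM `levels`, `distance`, angles | 64, 1, {0°,45°,90°,135°} | — | the co-occurrence construction is unspecified in the source; these are the common defaults (symmetric, normalized, per-angle matrices averaged) |
| `alpha` | 0.05 | — | the published screening threshold; a Benjamini–Hochberg flag is deliberately absent (the source screens raw) |
| `ntree`, `mtry` grid | 300, $1..\min(100,p)$ | — | published; the grid is capped at $p \le 65$ |
| `cv_folds` × `cv_repeats` | 10 × 3 | — | published |
| `train_fraction` | 2/3 | — | published split, applied at fruit level |
| `k_top` | 10 | — | published simplified-model size |
| `importance_reps` | 5 | — | permutation repetitions; only the MSE criterion is published |

## Numerical and design choices

* **Otsu** maximizes between-class variance over the 256-bin histogram;
  the first maximizing level is taken on ties, and a constant index image
  is rejected rather than guessed at.
* **Cleaning is idempotent by construction**: small-object removal never
  drops the largest component, and the opening is a true morphological
  opening (erosion then dilation by the same disk), so
  `clean(clean(m)) = clean(m)` — a property the suite checks on random
  blobs.
* **Hue statistics are linear** on $[0, 360)$ by default. Fruit hues here
  live in 50–110°, far from the wrap-around; a circular-statistics
  treatment was considered and rejected as an unpublished complication.
* **Channel ranges are native** (L in 0–100, a/b signed, S/V in 0–1, H in
  degrees), not 8-bit-rescaled; the source does not state its scaling, and
  native units keep the statistics interpretable.
* **ASM vs energy**: both are listed as separate parameters; we implement
  ASM $= \sum P^2$ and energy $= \sqrt{\text{ASM}}$, the convention that
  distinguishes them.
* **Morphology geometry is pixel-consistent**: area is the pixel count;
  the convex hull is taken over the *corners* of boundary pixels so the
  hull always covers the pixel squares and solidity $\le 1$ holds exactly;
  the minimum-area rectangle comes from rotating calipers on that hull;
  the minimum enclosing circle is Welzl's algorithm; fitted-ellipse axes
  come from second central moments with the $1/12$ pixel-variance
  correction ($\text{MA} = 4\sqrt{\lambda_1}$).
* **Ties**: CV-RMSE ties pick the smallest `mtry` (cheaper, lower
  variance); importance ties rank by the fixed parameter number.
* **Degenerate pairs** (constant feature or trait, $n < 3$) are flagged
  unusable and can never be selected — silence is treated as a bug.
* **"Each image was considered as a single RF model"** in the source is
  not interpretable as written; this package fits one forest per internal
  trait, consistent with the per-trait results table. Whether the
  published accuracy values are CV or held-out figures is likewise
  ambiguous ("three groups" vs "10-fold"), so reports carry both.
* **Colour-card correction and the "image-like enhancement algorithm"**
  of the source's preprocessing are undescribed; an optional gray-world
  white balance (`gray_world()`, off by default) is the only stand-in.

## Known limitations

* The forest predicts within the convex hull of training responses
  (averages of node means), so extrapolation beyond the training envelope
  is structurally impossible — acceptable for a monitoring application
  inside the cultivar's envelope.
* Fixed illumination is assumed, as in the source's photo box; natural
  light robustness is future work there and out of scope here.
* The synthetic netting is isotropic thresholded noise; real netting has
  ridge structure whose GLCM signature differs, so texture parameters
  carry weaker synthetic signal than colour parameters.
* Multi-fruit frames, shadow removal, and rank/partial correlations are
  non-goals.
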