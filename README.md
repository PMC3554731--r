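# nucleidict

Detection of individual cell nuclei in single-channel fluorescence
micrographs (e.g. DAPI-stained slides), built for the hard cases: touching
clusters, uneven illumination, apoptotic clutter and noisy low-exposure
images.

## The method

Foreground segmentation and nucleus individualization are solved *jointly*
as one convex problem. A relaxed labeling `u ∈ [0,1]` and per-radius
coefficient maps `t_r ∈ [0,1]` (one map per candidate radius in a
dictionary of binary disk atoms) minimize

```
E(u, t) = TV(u) + mu * <u, s> + lambda * ||t||_1 + (alpha/2) * ||u - D t||²
```

where `s(x) = (c1 − f(x))² − (c2 − f(x))²` is the active-contour-without-
edges data term (`c1`, `c2` estimated by Otsu thresholding), `TV` is
isotropic total variation, `D t = Σ_r k_r * t_r` synthesizes a segmentation
from disk atoms, and the `ℓ1` penalty is the convex surrogate for the
nucleus count. Convexity makes the result independent of initialization.
A multi-stage detection chain (dominant-radius map, merged coefficient map,
Otsu binarization, morphological closing, clutter masking by oversized-disk
opening, 8-connected components, greedy non-maximum suppression) turns
`(u, t)` into one centroid + radius + score per nucleus. Evaluation
follows the standard centroid-matching protocol: one-to-one matches within
3.2 µm, pooled precision/recall/F-measure, per-image count RMSE, and a
global Dice coefficient against a ground-truth mask.

A deterministic synthetic-micrograph generator with exact ground truth
(touching pairs, illumination gradients, clutter blobs, blur, noise) makes
the whole pipeline testable without any external data.

## Worked example

```r
library(nucleidict)

fx  <- generate_fixture(fixture_config(dim = c(128, 128), n_nuclei = 8, seed = 42))
res <- detect_nuclei(fx$image, run_config(r_min = 8, r_max = 12))
res$detections
#> # A tibble: 8 × 5
#>    x_px  y_px radius_px score  area
#>   <dbl> <dbl>     <dbl> <dbl> <int>
#> 1  25.3  88.3         9 0.838     3
#> 2  37.7 110.          9 0.805     3
#> 3  64.7  19.7         9 0.727     3
#> 4  32.7  11.7         9 0.697     3
#> 5 107    88.5         9 0.663     2
#> 6  98.3  11.3         9 0.662     3
#> 7 109   106.          9 0.614     2
#> 8  86.3  59.3         9 0.585     3

evaluate(list(res$detections), list(fx$truth),
         list(threshold_u(res$segmentation$u, 0.5)), list(fx$truth_mask))
#>   n_images tp fp fn precision recall f_measure rmse  dice
#> 1        1  8  0  0         1      1         1    0 0.887
```

Each detection row is one nucleus: `x_px`/`y_px` are its 0-based centroid
(x = column), `radius_px` its dominant dictionary radius, `score` the mean
preprocessed intensity of its candidate component. All 8 nuclei are found
with no false positives; the global Dice of 0.887 against the pre-blur
truth mask reflects the expected shrinkage of the segmented region by about
the blur width. `tidy()`/`glance()` summarize the fit, and
`autoplot(res$segmentation)` / `plot_detections()` draw it.

A command-line wrapper ships in `inst/cli/nucleidict`
(`detect`, `evaluate`, `fixtures` subcommands over TIFF/CSV/YAML files).

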