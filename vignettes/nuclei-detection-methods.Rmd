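---
title: "Dictionary-regularized convex active contours for nuclei detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary-regularized convex active contours for nuclei detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleidict)
```

## The problem

DAPI-stained cell nuclei in fluorescence micrographs are bright, roughly
circular blobs on a dark background. Counting and localizing them is routine
but hard to automate when nuclei touch in clusters, when illumination varies
across the field of view, when apoptotic debris glows alongside healthy
nuclei, and when exposure times are short and noisy. Segmenting foreground
from background and then splitting the segments is fragile, because the
splitting step only ever sees the segmentation, not the image.

`nucleidict` couples the two tasks in one convex objective. A relaxed
labeling $u : \Omega \to [0,1]$ plays the role of the segmentation; a stack
of coefficient maps $t_{r}(x) \in [0,1]$, one map per candidate nucleus
radius $r$, encodes where disk-shaped nuclei sit. The synthesis operator

$$ (Dt)(x) \;=\; \sum_{r} (k_r * t_r)(x), $$

with $k_r$ the binary disk of radius $r$, turns coefficients into the
segmentation such coefficients would generate. The joint energy is

$$ E(u, t) \;=\; \mathrm{TV}(u) \;+\; \mu \,\langle u, s\rangle \;+\;
   \lambda \,\lVert t \rVert_1 \;+\; \frac{\alpha}{2}\,\lVert u - Dt
   \rVert_2^2, $$

where $s(x) = (c_1 - f(x))^2 - (c_2 - f(x))^2$ is the
active-contour-without-edges data term with expected foreground/background
intensities $c_1 > c_2$, $\mathrm{TV}$ is isotropic total variation
(forward differences, Neumann boundary), the $\ell_1$ term is the convex
surrogate for the number of nuclei, and the quadratic term softly ties the
labeling to the disk model. Because the tie is soft, nuclei that deviate a
little from a disk, or touch their neighbors, are still representable. All
four terms are convex, so the minimizer — and any thresholding of it — does
not depend on the initialization.

Thresholding $u$ at any level in $(0,1)$ yields a binary segmentation that
minimizes the corresponding binary problem; the package uses 0.5 by
default.

## Parameters that matter

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `mu` | data-term weight vs. TV | 2 | — |
| `lambda_sparsity` | $\ell_1$ weight | `0.05 * median atom area * alpha` | — |
| `alpha_coupling` | strength of the $u \approx Dt$ tie | 0.5 | — |
| `r_min`, `r_max`, `r_step` | dictionary radius range | 8–12, step 1 | px |
| `norm_radius` | local normalization disk | `1.5 * r_max` | px |
| `gamma` | gamma-correction exponent | 2 | — |
| `u_threshold` | labeling binarization level | 0.5 | — |
| `match_radius_um` | evaluation match radius | 3.2 | µm |

A nucleus of radius $r$ survives segmentation roughly when its data gain
$\mu\,\lvert s\rvert\,\pi r^2$ exceeds its TV perimeter cost $2\pi r$ plus
the sparsity charge. With `mu = 1` that bar sits high enough that nuclei
dimmed to about half contrast by uneven illumination are dropped by the
*exact* minimizer — not by optimizer failure — which we observed directly on
the synthetic suite. The default `mu = 2` keeps such nuclei while leaving
background (where $s > 0$ is large) untouched. Consequently the faintest
recoverable object shrinks with `mu`; users with very small or very faint
nuclei should raise it further.

`lambda_sparsity` scales with the median atom area times `alpha_coupling`
so that the per-nucleus sparsity charge stays a fixed fraction (5%) of the
least-squares gain of placing one atom; a single well-matched atom then
settles near coefficient $1 - 0.05 = 0.95$.

The normalization radius must be large enough that the disk around any
pixel contains at least one nucleus, since the local maximum serves as the
local illumination estimate; in sparse fields this assumption fails and
empty background far from all nuclei is amplified, which is a known
limitation of max-based normalization rather than a tunable defect.

One property of the preprocessing is worth recording: a pure power gamma is
monotone increasing, so it commutes exactly with the local-max
normalization (the local maximum of $f^\gamma$ is the local maximum of $f$
raised to $\gamma$). The pipeline applies normalization first by
definition, but the reversed order produces the same image up to floating
point, and the test suite asserts that equality rather than a fictitious
difference.

## Optimization

The energy is minimized by alternating exact-subproblem descent:

* **Labeling update.** The $u$-subproblem (TV + linear + quadratic over the
  box $[0,1]$) is handled with primal-dual proximal iterations: a dual field
  absorbs the nonsmooth TV term exactly, and the box constraint — a
  piecewise-linear barrier whose minima are the interval endpoints — enters
  through exact projection in the primal proximal step. The dual field is
  warm-started across outer iterations. Each call ends with a backtracking
  line search on the *exact* subproblem energy, so the energy cannot
  increase. (An earlier Newton/lagged-diffusivity variant froze on flat
  regions, where the TV weights $1/\lvert\nabla u\rvert$ diverge at the
  constant initialization; the primal-dual form has no such degeneracy.)

* **Coefficient update.** Each sweep solves, for every coefficient
  simultaneously, the scalar optimality condition with all other
  coefficients held fixed: the unconstrained solution
  $\mathrm{soft}(\langle a, \text{residual}\rangle, \lambda/\alpha) /
  \lVert a\rVert^2$, clipped to $[0,1]$ because a quadratic is monotone on
  any interval not containing its extremum. Simultaneous updates of
  heavily overlapping atoms overshoot, so the sweep moves along the
  candidate direction with an exact line search (the quadratic part is
  closed-form in the step), plus Nesterov extrapolation between sweeps with
  restart whenever a step would raise the subproblem energy. FFTs of the
  disk kernels are precomputed once per image, making each sweep a handful
  of FFT products.

Both guards compare exact energies, so the recorded `energy_trace` is
non-increasing to machine precision — this is asserted, not hoped for, in
the tests. Iteration stops when the energy is flat to a relative `tol`
(default `1e-5`) over a five-iteration window (momentum can plateau briefly
before dropping again), or after `max_outer_iters` (default 300).
Convexity makes the result initialization-independent; the suite checks
that starting from $u \equiv 0$ and $u \equiv 0.5$ yields identical
thresholded segmentations.

With `lambda_sparsity = 0` and `alpha_coupling` near zero the model reduces
to plain convex active contours without edges, and on clean high-contrast
disks its thresholded labeling equals the Otsu mask exactly — a degeneration
the suite also checks.

## Detection chain

The $\ell_1$ surrogate spreads a little mass around each center instead of
producing one spike per nucleus, so centroids are extracted by a dedicated
chain: (1) per-pixel *dominant radius* = the radius with the largest
coefficient, ties toward the smaller; (2) *merged map* $T = \sum_r t_r$,
which peaks at nucleus centers; (3) binarize $T$ (Otsu over its strictly
positive values by default); (4) morphological closing (disk, radius 2 px)
so fragments of one nucleus merge; (5) intersect with a *clutter mask* —
the thresholded $u$ minus its opening by a disk larger than any legal
nucleus (default $1.5\,r_{max}$), which removes oversized objects such as
apoptotic debris; (6) 8-connected components become candidates, scored by
the mean preprocessed intensity over their pixels, with centroid the
unweighted pixel mean and radius the modal dominant radius; (7) greedy
non-maximum suppression: accept the best-scoring candidate, discard every
remaining candidate whose centroid lies within the accepted candidate's
dominant radius, repeat. Score ties break toward larger area, then
row-major centroid order, so the chain is fully deterministic.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` renders disks at configurable radii and contrast,
places a chosen fraction of them in touching pairs or chains (boundary
contact, overlap below 2 px, centers at least 2 px apart so ground truth
stays unambiguous), multiplies by a linear illumination ramp, optionally
adds oversized clutter blobs, blurs with a Gaussian kernel and adds clipped
Gaussian noise. All randomness flows from one explicit seed through a
private RNG stream, so samples are bit-reproducible and the caller's RNG
state is untouched. Low exposure times can be emulated by shrinking the
foreground/background contrast while raising the noise.

It does **not** model Poisson shot noise, intra-nucleus texture,
non-circular nucleus shapes (e.g. horse-shoe shaped neutrophil nuclei),
bleed-through, or dye smears from ruptured nuclei. Passing the synthetic
suite therefore demonstrates correct behavior under the geometric and
radiometric degradations above, not performance on any particular real
specimen.

Default suite conditions mirror the synthetic benchmark setting: 256×256
images, 30 nuclei of 20 px diameter, 30% touching, blur σ = 2 px, noise
sd 0.05, dictionary radii 8–12 px. These sizes keep the whole 10-image
suite within a few minutes on one core; the test suite uses smaller grids
(48–128 px) for property checks.

## Numerical choices and degenerate inputs

* Disk membership is the closed Euclidean disk (distance $\le r$); a
  radius-2 atom has exactly 13 pixels.
* Synthesis uses zero padding: a disk centered near the border contributes
  its clipped part, preserving linearity. The FFT fast path is checked
  against the direct convolution to $10^{-10}$.
* Constant images short-circuit: segmentation warns and returns an empty
  result instead of running on a degenerate histogram.
* An all-zero image passes through normalization unchanged, with a warning,
  rather than dividing by zero; the local-max floor is
  $10^{-6}\,\max(f)$ by default.
* `gamma < 1` is rejected: it would amplify low intensities, contradicting
  the purpose of suppressing apoptotic dye.
* Ground-truth matching is one-to-one at 3.2 µm, accepting candidate pairs
  closest-first, which is order-independent; on small random sets it agrees
  with an exhaustive assignment oracle. Adversarial configurations where
  greedy matching is suboptimal by one pair are possible in principle but
  did not occur across the tested sets.
* Dictionary construction always includes `r_max`, appending it when the
  arithmetic radius sequence misses it.

## Known limitations

* Dice on blurred fixtures plateaus near 0.89: blur moves the
  Otsu-estimated foreground intensity down and the recovered region shrinks
  by roughly the blur width relative to the pre-blur truth disks. Centroid
  detection is unaffected.
* Very small (radius ≲ 4 px at default `mu`) or very faint nuclei fall
  below the TV-vs-data bar discussed above.
* The suppression radius in non-maximum suppression is the accepted
  candidate's radius alone (not the sum of both radii) — the literal rule —
  so two *detected centers* closer than the smaller radius can in principle
  both survive only if the stronger one is processed first.
* Processing is 2-D, single-channel; there is no 3-D or multi-channel
  support, and no per-nucleus instance masks (evaluation is centroid-based
  plus one global Dice).
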