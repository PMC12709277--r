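---
title: "Segmenting phase-contrast stem cell images with adaptive thresholds and halo correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting phase-contrast stem cell images with adaptive thresholds and halo correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Phase-contrast microscopy converts the phase shifts that transparent, live
cells impose on light into visible amplitude differences, so adherent stem
cells can be monitored without stains that would compromise viability. The
optics, however, surround every specimen with a bright *halo*: along a ray
from outside a cell toward its interior, intensity rises through the halo
to a ridge and then falls as the true boundary is crossed. The halo blurs
the boundary, and cell/background intensities overlap, so a single global
threshold on raw intensity segments these images poorly.

`halocell` implements a four-stage pipeline for this setting:

1. **Local-contrast preprocessing.** The gray image $I$ is transformed to
   $C = \dfrac{w * I^2 - (w * I)^2}{w * I}$, where $w$ is a small Gaussian
   window (default $3\times3$, $\sigma = 0.8$) and $*$ is 2-D convolution:
   the windowed variance over the windowed mean. Textured cell bodies and
   boundary/halo regions have high local variance and map to high contrast;
   smooth background maps to values near zero regardless of the local
   illumination level, which makes the representation robust to shading.
2. **Adaptive thresholding.** From the integer-binned histogram of $C$
   (smoothed with a centered moving average, default width 5) two features
   are read: the peak position $M_p$ (gray level of the global maximum,
   ties broken toward the lowest bin) and the rate of rise $\beta$ (maximum
   forward difference of the smoothed histogram on the ascent from the
   first populated bin to the peak, normalized by the pixel count and
   scaled by 1000). The threshold is
   $$T = M_p + k \frac{M_p^2}{255}\Big(\frac{\beta^l}{\beta_u} - 1\Big),$$
   with $l = 2$, $k$ a per-dataset adjustment parameter and $\beta_u$ the
   maximum rate of rise over the dataset. $M_p$ is the reference point:
   when $\beta^l = \beta_u$, $T = M_p$ exactly; images whose histogram
   rises more gently than the dataset's steepest get a threshold pulled
   below the peak, i.e. a more foreground-inclusive segmentation. $T$ is
   clamped to $[0, \max C]$ before use, and foreground is $C \ge T$.
3. **Area constraint.** 4-connected foreground components smaller than
   `min_area` are removed, and background holes (4-connected background
   components not touching the image border) smaller than
   `fill_holes_below` are filled. The operation is idempotent.
4. **Halo correction.** The mask contour is moved along the intensity
   surface in the eight compass directions and stops where the gradient
   turns negative — the halo ridge, the rise-then-fall transition that
   marks the boundary.

Pixel-level evaluation (accuracy, recall, precision, F1 from the confusion
matrix), confluency (foreground area fraction, $(TP+FP)/N$) and confluency
error against a staining-derived standard complete the toolkit, together
with a seeded phantom generator that makes every stage testable without
microscope data.

## Halo correction in detail

The stopping rule is directional: a step is taken only while the gradient
along it exceeds `gradient_epsilon`. Two traversal senses are provided,
because an initial contour can sit on either side of the ridge:

* **grow** (default of `halo_correct()`): every background 8-neighbor `q`
  of a foreground pixel `p` with `img[q] - img[p] > eps` joins the
  foreground. The contour climbs the halo ramp outward and freezes where
  all outward gradients are non-positive — at the ridge. Out-of-bounds
  neighbors read as $-\infty$, so growth halts at the image border.
* **shrink** (used by the phantom profile, where the coarse mask
  over-covers): a contour pixel `p` with background at `p + d` retreats
  only while *every* such exposure direction still ascends inward
  (`img[p - d] - img[p] > eps`). Requiring all directions to ascend stops
  the retreat at the ridge instead of letting flat tangential gradients
  nibble along it. In shrink mode the image border is *not* treated as
  background adjacency: a border is not evidence of a cell boundary, and
  treating it as one would erode border-clipped cells from the image edge
  inward.

Freezing is stateless: each pass re-examines the current contour, and the
algorithm stops when a pass changes nothing or after `max_iterations`
passes (default 20), so the contour can move at most `max_iterations`
pixels (chessboard distance). A run that converged by the gradient
condition is a fixed point: rerunning it changes nothing.

`gradient_epsilon` defaults to 0 (strict ascent). On noisy surfaces a
slightly negative value lets the contour ride through flat stretches; the
phantom profile uses $-0.5$ on the Gaussian-smoothed intensity, where the
residual noise standard deviation is about 1 gray level.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `window_side`, `sigma` | px | 3, 0.8 | preprocessing window; 3x3 keeps boundaries sharp |
| `smooth_width` | bins | 5 | histogram smoothing; stabilizes $M_p$, $\beta$ under noise |
| `k` | — | per dataset | threshold adjustment; fitted by `calibrate_threshold()` |
| `l` | — | 2 | exponent constant of the threshold model |
| `beta_u` | $\beta$ units | per dataset | dataset maximum rate of rise |
| `min_area` | px | 64 | removes noise specks |
| `fill_holes_below` | px | 64 (400 in the phantom profile) | fills interior gaps; keep below typical inter-cell pocket size |
| `max_iterations` | passes | 20 | halo-correction travel budget |
| `gradient_epsilon` | intensity | 0 | stopping strictness |

Shipped profiles: `"c2c12"` ($k = 0.86$, $\beta_u = 30.99$, $M_p = 276$)
and `"hmscs"` ($k = 1.68$, $\beta_u = 27.45$, $M_p = 209$) carry the
published per-dataset settings for the two benchmark datasets; note their
$M_p$ values exceed 255, consistent with contrast images of 16-bit sources
not being bounded by the 8-bit range. Per-image estimation of $M_p$ is the
default; `fixed_mp = TRUE` pins the profile value, since a per-dataset
table entry admits either reading.

## The phantom generator

`generate_scene()` renders what the halo-correction stage needs to be true
of real images: radially perturbed cells whose interiors sit at 75% of a
background level of 120, with pixel-scale Gaussian mottling
(`cell_texture_sigma = 8`) standing in for intracellular texture; a halo
that rises from the boundary to 1.5x background at `halo_width / 2` (2 px)
outside the boundary and decays back to background by `halo_width` (4 px),
cosine-tapered so gradients are informative at pixel scale; a planar
illumination tilt (10% across the field); and Gaussian sensor noise
($\sigma = 3$). Along any ray from a cell center the noiseless intensity
is non-increasing from the ridge inward and from the ridge outward, and
the intensity maximum sits strictly outside the true boundary — the
structure the stopping rule exploits. Scenes are bit-identical under a
fixed seed. Field-of-view defaults (256x256, 12 cells, radii 14–24 px)
were chosen once as a realistic 10x stem-cell field; `generate_dataset()`
can instead bisect cell radii (doubling the cell count when needed) until
a requested true confluency is met within 0.03.

What the phantom does *not* emulate: Zernike optics (the halo is a
geometric profile, not a simulated point-spread function), structured
cytoplasm, mitotic morphologies, shot noise, or instance identity
(overlapping cells merge in the truth mask, consistent with pixel-level
evaluation). Passing phantom tests therefore demonstrates that the
pipeline recovers boundaries from rise-then-fall halo structure under
noise, tilt and texture — not that it reproduces any particular
microscope's statistics.

### The phantom profile

Phantom scenes are 8-bit and texture-poor compared with real tissue, so
their contrast histograms concentrate near zero: the integer-binned peak
is bin 0 and $\beta = 0$ for every scene. The `"phantom"` profile
therefore pins the peak (`fixed_mp = TRUE`, $M_p = 0.3$ — in the gap
between background contrast, about 0.06, and cell-interior contrast,
about 0.5) and keeps the published C2C12 adjustment $k = 0.86$; with
$\beta = 0$ the threshold reduces to $M_p - k M_p^2 / 255 \approx 0.30$.
These values were fixed once by inspecting seeded calibration scenes and
running the package's own grid calibration, the same per-dataset fitting
the benchmark profiles embody, and are not revisited per image. The
profile raises `fill_holes_below` to 400 (sub-threshold interior gaps are
small; inter-cell background pockets are usually larger) and runs halo
correction in shrink mode on the smoothed intensity, because the
low-threshold coarse mask over-covers: it includes the halo band out to
where contrast decays into noise, a few pixels outside the ridge.

Because the stopping rule by construction lands on the ridge, which sits
`halo_width / 2` (2 px) outside the true boundary, segmentations carry a
small dilation bias; with the default radii this costs a few points of
precision and makes the confluency estimate a mild overestimate. The bias
is a property of the published stopping rule, not of the implementation.

## Numerical and degenerate-input choices

* Denominator stabilizer $10^{-6}$ in the contrast transform: an all-zero
  image yields an all-zero contrast image rather than 0/0.
* Reflect (edge-repeating) padding at borders; zero padding would
  manufacture dark borders that corrupt $\beta$.
* Tiny negative contrast values from floating-point cancellation are
  clamped to 0.
* Histogram peak ties break toward the lowest bin; a single-bin histogram
  has no ascent and $\beta = 0$.
* When $\beta = 0$ the correction term $\beta^l/\beta_u$ is taken as 0 by
  continuity without requiring $\beta_u > 0$; this keeps calibration
  well-defined on datasets whose images all have $\beta = 0$ (then
  $\beta_u = \max_i \beta_i = 0$). A positive $\beta$ with
  $\beta_u \le 0$ is an error.
* Metric ratios with zero denominators are undefined (`NA`), distinct
  from 0, and excluded from batch means with the exclusion count
  reported. Both per-image means and pooled-pixel metrics are available,
  since an aggregate over a dataset admits either reading.
* The headline confluency error is the absolute difference; the signed
  value is retained for diagnostics.
* Calibration ties break toward the smallest `k` on the sorted grid.

## Validation scale

The test suite validates the contrast transform against a double-loop
brute force (random 8x8 images, $10^{-9}$ absolute), the threshold model
against its closed-form identities, the metrics against exhaustive pixel
loops (random 16x16 pairs), halo correction against radial-argmax oracles
on synthetic disks, and the full pipeline on ten 256x256 phantom scenes
spanning confluencies 0.1–0.5, where it checks mean pixel F1, mean
absolute confluency error, and that skipping preprocessing strictly
degrades F1. These sizes keep the default suite fast while covering every
code path; the same computations at larger sizes only sharpen the
estimates.

## Known limitations

* The threshold model's $M_p^2/255$ scale ties it to 8-bit-like value
  ranges; low-dynamic-range contrast images need a pinned $M_p$ (as the
  phantom profile does) or recalibration.
* Ridge-stopping dilates masks by about half the halo width; applications
  needing unbiased area estimates should correct for it.
* Pixel-level only: touching cells are not split into instances.
* Very high confluency fields, where halos merge and background pockets
  close up, degrade both thresholding and hole-filling heuristics.

## A worked example

```{r example}
library(halocell)

scene <- generate_scene(phantom_config(seed = 7))
res <- segment_image(scene$image, pipeline_config(profile = "phantom"))
res$log$confluency            # estimated confluency
scene$true_confluency         # generator ground truth

m <- compute_metrics(confusion_counts(res$mask, scene$truth))
unlist(m)
```
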