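# halocell

Segmentation of adherent stem cells in phase-contrast microscopy images,
for cell-culture labs and image-analysis pipelines that need confluency
estimates without staining. Phase contrast makes transparent live cells
visible but rings every cell with a bright **halo** artifact whose
intensity rises away from the cell to a ridge and then falls back to
background — which blurs the true boundary and defeats plain global
thresholding.

`halocell` implements an interpretable, lightweight pipeline:

1. **Local-contrast preprocessing** — the gray image *I* becomes
   *C = (w∗I² − (w∗I)²)/(w∗I)* with a 3×3 Gaussian window *w*: windowed
   variance over windowed mean, high on cell texture and boundaries, near
   zero on smooth background regardless of illumination.
2. **Adaptive threshold** — from the histogram of *C*, the peak position
   *Mₚ* and rate of rise *β* feed
   *T = Mₚ + k·(Mₚ²/255)·(βˡ/βᵤ − 1)* (with *l* = 2, per-dataset *k* and
   dataset-maximum rise rate *βᵤ*); foreground is *C ≥ T*.
3. **Area constraint** — removes small 4-connected components, fills
   small enclosed background holes.
4. **Halo correction** — moves the contour along the intensity surface in
   the eight compass directions and stops where the gradient turns
   negative, i.e. on the halo ridge at the cell boundary.

Evaluation utilities compute pixel-level accuracy, recall, precision and
F1 from the confusion matrix, confluency as the foreground area fraction
*(TP+FP)/N*, and the confluency error against a staining-derived standard.
A seeded synthetic **phantom generator** renders phase-contrast-like
scenes (textured dark cells, rise-then-fall halos, illumination tilt,
sensor noise) with exact ground truth, so every stage is testable without
microscope data. The methods vignette
(`vignettes/halocell-methods.Rmd`) documents the model, its parameters and
the design choices.

## Worked example

```r
library(halocell)

scene <- generate_scene(phantom_config(seed = 7))
scene
#> <phantom_scene> 256 x 256, 12 cells, true confluency 0.175

res <- segment_image(scene$image, pipeline_config(profile = "phantom"))
res
#> <segmentation_result> beta 0, m_p 0.3, T 0.2997, 20 halo iter, confluency 0.193

compute_metrics(confusion_counts(res$mask, scene$truth))
#> <segmentation_metrics> accuracy 0.9458  recall 0.8949  precision 0.8140  f1 0.8526
```

The log line reads: the contrast histogram of this low-dynamic-range
synthetic scene has no ascent (*β* = 0), the phantom profile pins the peak
at *Mₚ* = 0.3, the threshold lands at 0.2997, halo correction ran 20
contour passes, and the estimated confluency is 0.193 against a ground
truth of 0.175 — a mild overestimate, because the stopping rule lands on
the halo ridge, which sits half a halo-width outside the true boundary.

Batch use mirrors a shell workflow: `cmd_simulate()`, `cmd_segment()`,
`cmd_evaluate()`, `cmd_calibrate()` operate on directories (a thin
`Rscript` front end with the same verbs lives in `inst/cli/halocell.R`).
Profiles `"c2c12"` and `"hmscs"` carry the published parameter settings of
the two benchmark datasets; `calibrate_threshold()` fits *k* and *βᵤ* for
a new dataset from a few annotated images.

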