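# vescap

Quantification of Golgi-derived vesicle capture at the yeast bud neck, and
kinetic mapping of cisternal maturation.

## The problem

Resident Golgi proteins in budding yeast stay in the Golgi by continual
recycling between maturing cisternae. One way to ask *which vesicles carry
which resident protein* is a capture assay: a septin at the bud neck is tagged
with FKBP, a resident Golgi protein is tagged on its cytosolic tail with FRB,
and rapamycin crosslinks the two — so transport vesicles carrying the
FRB-tagged protein become trapped at the bud neck, away from Golgi cisternae.
A second, GFP-tagged protein is then scored for co-capture. `vescap`
implements the quantification machinery for this assay and its companions:

* **Capture fraction.** For a 3-channel confocal z-stack (red septin, green
  cargo, blue Golgi marker), a per-slice septin mask is built from the red
  channel at the "Lower" threshold of a deterministic threshold ladder, a
  generous Golgi mask from the blue channel at the lowest "Basement" level is
  subtracted from it, and the statistic is

  `capture_fraction = sum(green | modified septin mask) / sum(green | ROI)`,

  summed over every slice of the z-stack. Cells in which the subtraction
  removes ≥ 65% of the septin mask are flagged as QC failures (cisternae at
  the neck) and excluded from means.
* **Kinetics.** Per-cisterna fluorescence traces are bleach-corrected
  (exponential fit), smoothed (boxcar), normalized to [0, 1], aligned at the
  half-maximum rise of a reference channel, and averaged; the cisternal
  residence time of a protein is the interval between its first and last
  visible signals (background + 3·SD for ≥ 2 frames, sub-frame interpolated).
  Condition comparisons (e.g. partial COPI inactivation) report group means,
  the fold change, and Welch's two-sided t test.
* **Capture-zone geometry.** For cryo-electron tomograms, the capture zone
  extends ±200 nm along the cell cortex from the bud-neck center and
  `zone_depth(48, 58) = 106` nm into the cytoplasm (the summed extended
  lengths of the tagged septin and the Kex2 cytosolic tail). A vesicle is
  putatively captured if any part of its membrane lies within the zone —
  equivalently, if the distance from its center to the closed zone is at most
  its radius.
* **Reporting.** Significance stars, blinded-name encryption for visual
  scoring, categorical tabulation, and scatter summaries (mean ± SD).
* **Synthetic data.** Generators for confocal capture scenes, maturation
  traces, and tomogram vesicle models with exact ground truth, so every
  stage is testable end to end.

## Worked example

```r
library(vescap)

# a synthetic capture scene with a known 7% true capture fraction
sc  <- generate_capture_scene(scene_config(capture_fraction = 0.07, rng_seed = 7))
res <- quantify_overlap(sc$stack, cell_id = "cell7", condition = "rapamycin")
res
#> <cell_capture> cell7: capture fraction 0.0668 (removed 0.3% of septin mask, QC pass)
sc$truth$true_capture_fraction
#> [1] 0.07

# residence-time comparison, control vs partial COPI inactivation
ctrl <- generate_residence_sample(15,  94, cv = 0.2, rng_seed = 101)
trt  <- generate_residence_sample(15, 140, cv = 0.2, rng_seed = 102)
compare_conditions(ctrl, trt)
#> <condition_comparison> fold change 1.589, Welch t = -6.768 (df 20.8), p = 1.14e-06 (****)

# cryo-ET capture-zone scoring of a synthetic tomogram model
tm <- generate_tomogram_model(tomogram_config(n_vesicles = 30, rng_seed = 3))
count_captured(tm$vesicles, tm$zone)$per_cell$n_captured
#> [1] 11
sum(tm$true_captured)   # surface-sampling ground truth agrees
#> [1] 11
```

The capture estimate (0.0668) recovers the generator's true fraction (0.07)
to well within the mask-edge error budget; the residence comparison resolves
the ~1.5-fold slowdown; the distance-based vesicle classifier reproduces the
dense surface-sampling labels exactly.

## Vignette

See `vignettes/vesicle-capture-quantification.Rmd` for the model
assumptions, parameter choices, and known limitations.
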