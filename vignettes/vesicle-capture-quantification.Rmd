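---
title: "Quantifying vesicle capture at the bud neck: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vesicle capture at the bud neck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vescap)
```

## The assay and its statistic

In the chemically induced dimerization capture assay, a bud-neck septin is
fused to FKBP and a resident Golgi membrane protein to FRB; rapamycin bridges
the two, so Golgi-derived transport vesicles carrying the FRB-tagged protein
are trapped at the septin ring. A GFP-tagged second protein co-captures only
if it travels in the same vesicles. The numerical readout is the **capture
fraction**: the fraction of total cellular green (cargo) fluorescence that
lies inside a septin mask from which a Golgi mask has been subtracted.

Three measurement choices define the statistic:

1. **Per-slice masks, summed across the z-stack.** Masks are thresholded per
   optical section and intensities are summed over all sections; because sums
   commute, this is identical to a whole-volume computation, and the package
   asserts that equality in its tests.
2. **Asymmetric thresholds.** The septin (red) mask uses a moderate "Lower"
   threshold; the Golgi (blue) mask uses the lowest "Basement" threshold so
   that essentially all visible Golgi signal is subtracted. The rationale is
   conservative: losing some captured-vesicle signal is acceptable, counting
   cisternal signal as captured is not. The statistic therefore tends to
   *underestimate* capture, and enlarging the Golgi mask can only lower it —
   a monotonicity the tests verify.
3. **The 65% QC rule.** If subtraction removes 65% or more of the septin
   mask, Golgi cisternae overlie the neck and the cell is excluded. The
   boundary is strict: a removed fraction of exactly 0.65 fails, 0.64 passes.

### The threshold ladder

The interactive tool this package models offers the user a menu of threshold
options; the generating algorithm is not published, so `vescap` defines its
own deterministic ladder and documents it as a stand-in. Within the ROI,
levels sit at `median + {2, 4, 8, 16} * s`, named Basement, Lower, Middle and
Upper, where `s = max(MAD, 0.05 * (max - median))`. The MAD is the natural
robust scale for continuous background, but it collapses to exactly zero for
count-valued backgrounds dominated by one value and for clean two-population
images; the range-based floor keeps the ladder finite and places "Lower"
between background and signal in the two-population case. A channel that is
constant within the ROI has no contrast and is rejected.

## Synthetic scenes: what they emulate and what they do not

`generate_capture_scene()` renders a 64 x 64 x 21 voxel, 3-channel stack at
60 nm pixels and a 300 nm z-step (the midpoint and step of typical yeast
volume imaging): a red septin ring (radius 450 nm) at the grid center, blue-
and green-labeled cisternae placed at least 1.1 um from the neck, and
point-like green captured vesicles on the ring. Structures are isotropic 3D
Gaussians (sigma 120 nm lateral, 350 nm axial — a simple PSF proxy) whose
kernels are renormalized over the grid, so placed photons are conserved
exactly before noise; the **true capture fraction is defined pre-noise on
photon budgets**, `vesicle green / total green`.

Noise is Poisson on expected counts with an optional clipped-Gaussian read
noise (off by default). The background defaults to 0.05 counts per voxel:
the capture fraction is computed on raw summed intensities, so the summed
ROI background enters the denominator, and the default photon budgets
(20,000 green photons per cisterna, 600,000 for the ring) were chosen so
that this bias stays an order of magnitude below the recovery tolerance. A
noise-free mode (`apply_noise = FALSE`, zero background) isolates the
residual mask-edge error: green vesicle fluorescence extends slightly beyond
the thresholded septin ring, costing a few percent of vesicle photons, which
is why noise-free recovery is specified at +/-0.01 absolute rather than
exactly. Published image levels are not characterized, so these defaults are
chosen for testability, not realism — passing recovery tests demonstrates
that the estimator is unbiased under the stated noise model, not that it is
robust to every real-world background.

What the generator deliberately does not emulate: optical aberrations beyond
Gaussian blur, deconvolution artifacts, cell autofluorescence structure,
cell-cycle geometry, or any maturation mechanism (traces are generated
separately as parametric trapezoids).

## Kinetic traces

A maturing cisterna recruits and then loses a tagged protein; the synthetic
profile is a trapezoid (default: arrival 30 s, 10 s rise, 50 s plateau,
10 s fall in a 160 s recording at 2 s frames), attenuated by
`exp(-bleach_rate * t)`, with Gaussian noise (SD 2% of the 100 AU amplitude)
and a per-cisterna Gaussian timing jitter (SD 3 s).

Processing conventions, each configurable:

* **Bleach correction** fits a single exponential to the log of a reference
  series (default: the channel sum) and divides it out, anchored at t = 0.
* **Smoothing** is a boxcar of 3 frames with shrinking end windows.
* **Normalization** subtracts a baseline — the 10th-percentile
  *order statistic* (type-1 quantile) of frames before the first provisional
  detection — divides by the resulting maximum, and clips to [0, 1]. The
  order-statistic baseline makes normalization exactly idempotent and
  affine-invariant, which interpolation-based quantiles do not guarantee.
* **Alignment** shifts each trace so the first upward half-maximum crossing
  of its normalized reference channel (linearly interpolated) sits at t = 0;
  traces without such a crossing are excluded with a warning. Averages are
  computed per grid timepoint over the traces that cover it, weighting each
  contributing cisterna equally (duration-weighted averaging is a defensible
  alternative; equal weighting matches the convention of plotting each
  cisterna as one trace).
* **Residence time** is the interval between the first and last visible
  signals, with "visible" operationalized as exceeding background + 3 x noise
  SD for at least 2 consecutive frames. Background defaults to the 25th
  intensity percentile and the noise SD to `mad(diff(x)) / sqrt(2)`, both
  scale-equivariant, so detection is invariant under positive rescaling. The
  boundary is refined by linearly interpolating the threshold crossing
  adjacent to the first/last qualifying frame: on a noise-free trapezoid
  visible from 10 s to 100 s this yields exactly 90 s, and on noisy jittered
  ensembles the mean absolute error stays under one frame (2 s). Traces with
  no qualifying frames are flagged undetected, never reported as zero.
* **Overlap windows** intersect two channels' visible intervals, extract
  10-15 s of padding on each side, and rescale each channel so its window
  maximum is exactly 1.

## Capture-zone geometry

The cryo-ET scoring rule builds a zone from two measured quantities: septin
rings extend about 200 nm along the cortex in each direction from the neck
center, and a trapped vesicle can sit at most one fully extended tether pair
from the membrane — `zone_depth(48, 58) = 106` nm for the tagged septin plus
the Kex2 cytosolic tail (83 nm for Sys1, 66 nm for Vrg4 analogously).

The cortex is an ordered 3D polyline with the cytoplasm side declared as an
explicit direction vector; construction refuses to guess an orientation. The
zone is the truncated +/-200 nm (arc length) sub-polyline swept into the
cytoplasm: formally the Minkowski sum of the segment with the cytoplasm-side
half-ball of radius `depth`. This is a closed 3D region — membership has a
per-segment closed form (a quadratic interval in the segment parameter
intersected with a half-space interval), and tangency counts as captured.
Whether the original scoring was performed in 3D or per tomographic slice is
not recorded; the 3D closed-region reading is implemented because "any part
of its membrane" is a statement about the sphere, and a 2D analysis is the
special case of a planar cortex and coplanar vesicle centers. Arc length is
measured along the polyline (geodesic on the modeled membrane trace).

`classify_vesicle()` scores a vesicle captured iff the distance from its
center to the zone is at most its radius; the distance combines the exact
membership test with a per-segment grid-plus-`optimize` minimization of the
half-ball distance. An independent reference route,
`classify_vesicle_sampled()`, samples 10^4 deterministic Fibonacci-lattice
points on the vesicle surface and tests membership directly; the two agree
on 100% of randomized vesicles against straight and curved cortices in the
acceptance suite. The sampled oracle can in principle miss grazing contacts
smaller than its lattice spacing (~0.03 nm penetration for a 25 nm vesicle),
which has negligible probability for randomly placed vesicles. Counts are
restricted to the non-secretory vesicle class (radii 17.5-30 nm) by default,
and are reported per lamella as modeled, with no extrapolation to the full
bud-neck volume.

## Statistics and reporting

All two-group comparisons use Welch's unequal-variance t test, two-sided
(reported p values in this line of work are not annotated with a direction;
two-sided is the conservative reading). `welch_t()` delegates to
`stats::t.test()` and the test suite verifies it against the closed form to
1e-12 relative. Degenerate input (two constant groups) yields t = 0, p = 1
when means agree and an explicit error otherwise; `compare_conditions()`
still reports the fold change in the degenerate case, with NA statistics and
a warning. Significance stars follow the conventional tiers (`****` below
1e-4, then `***`, `**`, `*` at 1e-3, 1e-2, 0.05). Scatter summaries use the
n-1 SD; single-value groups carry a `sd_defined = FALSE` flag rather than a
fabricated spread. Categorical scoring remains a human judgment: the package
supplies only display preparation (average projection, per-channel
saturation of 0.3/0.5/0.4% for red/green/blue, the x1.5 display scaling with
clipping, where a constant image maps to 0 to avoid a degenerate min-max),
keyed name blinding, and tabulation with per-condition fractions.

The replicated simulation of the partial COPI-inactivation comparison draws
15 residence times per group at means of 94 s and 140 s with a 20%
coefficient of variation. A single replicate's fold-change estimate has a
sampling SD near 7%, so the 10% agreement check is applied to the mean fold
change across 100 replicate seeds, while the power check (Welch p < 0.05)
is applied per replicate and required in at least 95% of them.

## Problem sizes and determinism

The validation suite runs 32 synthetic scenes (64 x 64 x 21 voxels) for
capture-fraction recovery, 50-trace ensembles for residence recovery, and
200 vesicle classifications against the 10^4-point oracle — sizes chosen so
the full suite completes in well under a minute while keeping Monte Carlo
margins wide. Every generator takes an explicit integer seed and restores
the caller's RNG state; identical configurations and seeds are bit-identical
across runs.

## Known limitations

* The threshold ladder is a declared stand-in for an unpublished interactive
  algorithm; absolute capture fractions depend on the chosen levels, though
  the Basement/Lower convention and the monotone underestimation property do
  not.
* Capture fractions are computed on raw intensities (no background
  subtraction), as in the modeled workflow; heavily background-dominated
  images will bias the denominator upward.
* Cell and ROI selection, cisterna tracking, and category assignment are
  upstream human steps; the package quantifies given ROIs and traces.
* The bleach model is a single exponential; multi-component bleaching will
  leave residual trends.
* Vesicles are modeled as spheres and the cortex as a polyline; highly
  non-spherical carriers or strongly curved 3D membrane patches would need a
  triangulated-surface extension.
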