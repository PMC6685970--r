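---
title: "Unrolled odor maps and innate-aversion analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unrolled odor maps and innate-aversion analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfmap)
```

# Overview

Activity across the olfactory bulb's glomerular layer (GL) is commonly
summarized as an *unrolled odor map*: in each coronal section the annular GL
is traced along its centre, cut open at the ventral edge, straightened into a
flat strip, and the strips are stacked anterior to posterior, aligned on the
dorsal-medial edge. Immediate-early-gene-positive (Egr1⁺) periglomerular
cells counted in 100-µm divisions along each strip then give a 2-D activity
map. Alongside the maps, innate aversion to odorants is quantified from
overhead video: the mouse body centroid is tracked frame by frame, its
distance to the odor source is normalized to 0 (source) … 1 (opposite wall),
and the *aversion index* is the time spent in the near third during an odor
trial minus the mean time control animals spent there with water.

`olfmap` implements both pipelines, the supporting group statistics, and
seeded synthetic-data generators that provide exact ground truth for every
stage. The `analysis/` scripts run the whole workflow; this vignette records
the models, conventions, parameter choices, and limitations.

# Unrolled odor maps

## Centerline tracing

The study traced GL centerlines manually in ImageJ. Here tracing is
automated, with `trace_centerline(manual = …)` accepting an operator
polyline to mirror the manual workflow. The automatic tracer:

1. thresholds the section (Otsu by default) and keeps the largest
   8-connected foreground component — the GL band;
2. casts rays from the band centroid at 1440 angles and takes the radial
   midpoint of the band run on each ray (sampled at 0.25-px steps with
   bilinear interpolation);
3. low-pass filters the resulting radius profile (24 Fourier harmonics by
   default). The GL outline is smooth at the section scale, while subpixel
   sampling noise, left unfiltered, inflates the polygonal arc length by
   over 1% and would shift every downstream column boundary.

The path is opened at the ventral edge reference point and ordered in the
direction of increasing polar angle, i.e. ventral → medial → dorsal →
lateral in image coordinates (y down). The source data do not state an
unrolling direction; this counter-clockwise convention (in medial view) is a
package choice and is recorded in the map metadata. Arc length is measured
in µm from the opening; the dorsal-medial reference point's arc position is
stored as the alignment landmark.

This polar tracer assumes the band is star-convex about its centroid, which
holds for coronal bulb sections and for the generator's jittered ellipses; a
strongly folded layer would need the manual-polyline route.

## Straightening and assembly

`straighten()` resamples the image along normals to the path at 1-px arc
steps (bilinear interpolation), the curved-layer analogue of ImageJ's
straighten function. Strip column *j* corresponds to arc length *j*·scale
µm; a straight horizontal path reproduces an axis-aligned crop bit-exactly,
which anchors the geometry tests. Near the centerline the map's Jacobian is
1 + O(offset·curvature), so integrated intensity is conserved to ~2% for
half-widths well under the radius of curvature — the regime of a 40-µm GL
band on a ~300-µm bulb.

`assemble_map()` stacks strips anterior (top) to posterior (bottom), shifts
each so the dorsal-medial landmark sits at a common x, and pads with an `NA`
no-data sentinel, never intensity 0, so padding can never masquerade as
signal. Sections are 20 µm thick, collected at 60-µm gaps; whether rows are
60 or 80 µm apart centre-to-centre is ambiguous in that phrasing, so the row
spacing defaults to 80 µm and is configurable metadata — it does not affect
any count.

Column binning stays in per-sheet coordinates (arc length from the ventral
opening); the landmark shift affects only the assembled raster. Both
per-sheet-row counts and a pooled summary are available, since published
histograms are per map.

## Cell detection and quantification

Detection follows the binarize → despeckle → watershed → size-filtered
particle chain: thresholding (Otsu default, overridable), removal of
components under 4 px², distance-transform watershed to split touching
blobs, then area filtering (default 10–200 px² at 1 µm/px; the synthetic
fixtures use 10–60 px² for their 3-px-radius nuclei). Centroids are
unweighted area centroids.

Counts use half-open 100-µm columns: column *j* is [100·j, 100·(j+1)) µm.
Response classes resolve the overlapping published ranges "5–15", "15–25",
"more than 25" as weak = [5, 15], medium = (15, 25], high = (25, ∞): "more
than 25" is strict, so 25 falls to medium, and 15 is assigned to weak to
make the classes a deterministic partition. The boundaries are
configurable. Heat-map rasters clip below 5 (black) and above 30 (red) with
a linear blue→red rainbow between.

The OCAM-negative dorsal territory — the region the histograms quantify — is
supplied as a per-row inclusive column interval, not inferred from stain
images. Because the strip runs ventral → dorsal → ventral, that territory
is a *central* interval with two boundary columns (both included); a
one-sided region is the special case `lo = 0`.

# Synthetic sections

`gen_section()` draws nucleus counts per fine angular bin as
Poisson(λ(θ)·Δs/100), places nuclei uniformly along the bin arc and
uniformly across the band (kept fully inside it), and renders: Gaussian
background (mean 50, sd 5 on a 0–255 scale), the GL band tissue at
intensity 110 (rasterized radially, symmetric about the centerline, so the
band's radial midpoint *is* the centerline), and uniform discs at 200 for
nuclei. The ground truth lists every nucleus with its analytic arc-length
coordinate and true column.

Two presets matter for validation:

* **Cleanly separable** (`min_sep = 12`, `column_guard = 5` µm): nuclei are
  at least 12 µm apart and their discs lie wholly inside one column and
  clear of the ventral cut. Under these conditions per-column recovery is
  *exact*, and that is the well-posed version of the claim: a blob
  straddling a column boundary (or the opening) has no unambiguous true
  column, so boundary-straddling placements are excluded from the exactness
  preset rather than adjudicated by a tie-break.
* **Touching pairs** (`touching_frac = 0.1`): ~10% of nuclei get a twin 1.5
  radii away; the watershed must split these, and recovery is asserted at
  ≥ 95%.

The generator emulates density variation along the layer and an OCAM
boundary; it does not emulate uneven illumination, staining gradients,
section tears, or out-of-plane tilt, so passing tests demonstrate the
geometry and counting chain, not robustness to histology artefacts.

# Behavioral analysis

## Tracking

Frames are auto-thresholded (one Otsu threshold from the first frame by
default — illumination is constant in the assay; per-frame thresholding is
available), blurred with a 3-px Gaussian, and re-binarized. The blur is the
tail-removal step: a 1-px-wide tail peaks at ≈ 0.13 after a σ = 3 blur of a
binary image and falls below the 0.5 re-binarization level, while a
radius-8 body disc erodes only ≈ σ²/2R ≈ 0.6 px at its rim (≈ 13% area).
The blur is computed as a separable convolution restricted to the
foreground bounding box (padded by 4σ), which is numerically identical to
the full-frame convolution there and keeps 15,000-frame trials tractable.
The body is the largest component within the size filter (default 100–2000
px²); frames without one are flagged and linearly interpolated, and > 20%
invalid frames is a tracking failure.

## Distance, occupancy, index

Normalized distance is 2-D Euclidean distance to the source point divided by
the perpendicular distance from the source to the opposite-side line
(axis-projection is available as an option; which the study used is not
stated). The near region is d̂ < 1/3, strict. Occupancy counts valid frames
in a half-open time window — the first-1-min window of a 25-fps trial is
exactly 1500 frames — divided by the frame rate. The aversion index is
T_odor − mean(T_DW) in seconds; negative = aversion.

## Synthetic trials

The walk is x_{t+1} = reflect(x_t + β·e^{−d/λ_odor}·û_away + σ·ε_t) in a
200 × 318 mm cage at 25 fps, 600 s, source at the middle of a short wall.
The exponential-repulsion drift is the test harness's stand-in for odor
avoidance — a monotone, single-parameter family chosen so that recovery
tests can ask for graded responses. Defaults: σ = 2.5 mm/frame (~62 mm/s,
a realistic exploration speed) and λ_odor = 30 mm, picked from the
stationary-density approximation exp(−(2βλ/σ²)·e^{−d/λ}) so that β ∈
{0, 0.5, 1, 2} spans indifference to strong avoidance with well-separated
mean occupancies. The β sweep uses the same replicate seeds for every β
(common random numbers), the standard paired design for comparing
simulated conditions. For a "strongly avoidant" agent whose suppression
covers the whole near third, a larger length scale (λ_odor ≈ 80 mm) is the
appropriate configuration, since the near third extends ~106 mm from the
source while the default drift acts over a few times 30 mm.

Rendered frames (320 × 180 px, body disc radius 8 px, 1-px tail, Gaussian
sensor noise) are generated lazily one frame at a time — a full trial is
never held in memory — with per-frame seeds derived from the trial seed so
any frame is reproducible in isolation. Reflection keeps the body disc
fully inside the cage, so every position is inside the cage bounds.

# Statistics

`ttest_from_summary()` recomputes two-tailed two-sample t-tests from
published mean/s.e.m./n triples: t = (m₁ − m₂)/√(sem₁² + sem₂²) with
Welch–Satterthwaite df, or the pooled-variance statistic with n₁ + n₂ − 2
df. Which flavor produced the published p-values is not stated, so both are
always reported; with n = 3 per group the two recomputed p-values for the
published class I and class II comparisons agree with the printed values to
well within the rounding of the summaries. `ttest_raw()` (via
`stats::t.test`) matches the summary route to 10⁻¹⁰ on derived summaries.
BH adjustment delegates to `stats::p.adjust(method = "BH")` after
validation, and the test suite checks it against a written-out step-up
brute force; multiple-testing families are always declared explicitly,
never inferred. `log2_norm()` maps zero signals to a configured floor
(default: half the smallest positive signal) since log₂ 0 is undefined and
the source convention is unstated. Fold changes add the +0.1 pseudocount to
both numerator and denominator. The dorsal-ventral distribution normalizes
positions by map length into 10 equal half-open segments, the last closed
at 1.

# Numerical choices and degenerate inputs

* Pixels are 0-based with half-open binning throughout; all physical
  quantities are µm, mm, and seconds.
* Bilinear interpolation everywhere; points outside the image sample as
  background and are counted in a warning.
* The ridge tracer falls back to lower interpolation thresholds on rays
  where the band is thinner than the sampling kernel (a 1-px ring is the
  degenerate case and traces to itself).
* Constant images have no automatic threshold and are rejected (blank
  behavioral frames are instead flagged invalid, since they are expected
  during a trial).
* Degenerate t-tests (both sems zero) return p = 1 for equal means rather
  than NaN.
* Problem sizes in the tests — sections of ~860 × 720 px with ~190 nuclei,
  ten clean section sets, two rendered 600-s videos, 2,000 null t-test
  simulations — were chosen as the smallest sets that exercise every
  code path with meaningful statistical power.

# Known limitations

* The tracer requires a star-convex, connected band; heavily damaged
  sections need manual polylines.
* Exact count recovery is defined for the cleanly separable preset only;
  real tissue has boundary-straddling and clumped cells, where recovery is
  a rate, not an identity.
* Single-animal tracking only; no pose estimation, and occlusions are
  handled only by interpolation.
* Maps are not registered across animals; cross-animal statistics operate
  on per-map summaries (histograms, column counts).
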