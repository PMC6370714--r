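---
title: "Methods: segmentation and quantification of spheroid microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and quantification of spheroid microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidseg)
```

## The problem

Cryosections of 3D spheroid cultures imaged by confocal
immunofluorescence are hard to segment with a single global threshold:
cells are densely packed, touch each other, and markers of interest are
often strongly enriched in the outermost cell layers. An automatic
threshold computed over such an image tends to sit between the dim
interior cells and the bright rim, so only the rim is detected. The
multistep routine in this package addresses exactly that regime, and the
surrounding functions quantify what spheroid studies report: rim-versus-core
enrichment, per-condition fluorescence, marker-positive cell fractions,
growth-area morphometry of phase-contrast series, and loading-control
normalized blot densitometry.

## The multistep segmentation routine

`multistep_segment()` applies, to a working copy of one raw channel:

1. **Median denoising** (`median_denoise`, radius 1.0 px). The footprint
   at radius r is the offset set `di² + dj² ≤ r² + 1`, so radius 1 is the
   full 3×3 square; edges are replicated. The implementation is an exact
   vectorized median (a sorting network in the 3×3 case) so it can be
   verified against a brute-force sliding-window oracle to machine
   precision.
2. **Contrast stretch** (`rescale_contrast`). A linear map of the
   `[saturation, 1 − saturation]` intensity quantiles onto `[0, 1]` with
   clipping. The default saturates **5% of pixels per tail**. This is the
   step that makes rim-bright scenes segmentable: clipping the brightest
   pixels compresses the rim so that the subsequent global threshold
   drops below the interior cells. With a much smaller saturation the
   threshold stays above the core and both this routine and the baseline
   miss interior cells entirely — on synthetic rim-4.3× scenes interior
   recall goes from 0.00 to ≈ 0.93 as the saturation rises to 5%. A
   constant image is returned unchanged with a notice, since the stretch
   is undefined.
3. **Automatic thresholding** (`binarize_auto`): isodata (default), Otsu,
   or mean, each computed on a 256-bin histogram of the observed range.
   Isodata iterates the threshold to the midpoint of the two class means;
   its fixed point on a two-delta histogram is the midpoint of the two
   values, which the tests assert. Foreground is `pixel > threshold`.
4. **Dilation** (`dilate_mask`, one pass of a 3×3 square). Recovers the
   dim outer part of a cell whose above-threshold core would otherwise
   fall under the particle size filter.
5. **Watershed splitting** (`split_watershed`). Euclidean distance
   transform of the mask; watershed labelling of the inverted distance
   map restricted to the mask. Seed maxima closer than
   `min_seed_distance` (default 5 px) or with less than 1 px of dynamic
   are merged, which prevents over-splitting from surface roughness. On
   masks with no touching objects the output partition equals plain
   connected components (tested).
6. **Particle size filter** (`filter_by_size`). Survivors must have
   `area ≥ 50` px by default. The published description says "larger
   than 50 pixels"; the inclusive reading is the default and the strict
   one is available (`min_area_strict`). Survivors are renumbered 1..K in
   raster order of first occurrence.

Two conventions apply everywhere: objects are **8-connected** (the
particle-analyzer convention), and all measurements are taken **on the
raw image** with `region_properties()` — the routine never mutates its
input, and the returned label map is aligned with the raw image so
intensities are measured without any quality loss from the processing
chain. Coordinates in tables are 1-based `(row, col)` with pixel centers
at integer positions, as is idiomatic in R.

A **no-structure guard** precedes thresholding: an automatic histogram
threshold splits even a pure-noise image near the middle of its noise
distribution, and at ~50% foreground density random fields percolate into
components far larger than any size filter. A field whose two isodata
classes differ by less than 4 robust (MAD) standard deviations is
therefore declared structureless and yields an empty label map. This is
the automated stand-in for the visual inspection step of interactive
workflows.

`simple_threshold_segment()` is the deliberately naive baseline: one
automatic threshold on the raw channel, connected components, size filter
— no denoising, stretch, dilation, or watershed. On rim-bright scenes it
finds the rim and a handful of bright specks while the multistep routine
also recovers the core; the acceptance suite asserts at least a two-fold
interior-recall advantage.

## Rim/core partition and enrichment

`spheroid_mask()` finds the section: heavy Gaussian smoothing (σ = 10 px)
of a reference channel, Otsu threshold, largest 8-connected component,
closing, hole filling (hollow cores stay inside the section), and a small
boundary-recovery dilation (disc of size `2·round(σ/4)+1`). The dilation
compensates a systematic few-pixel erosion of the boundary that
thresholding a σ-blurred, spotty intensity field produces; with it the
detected area stays within ±10% of truth across the tested densities.
Detection failure (a structureless field, or no credible component)
raises an error, or returns a full-frame mask with
`fallback_full_frame = TRUE` — the monolayer path `run_pipeline()` uses.

`rim_partition()` splits the section exactly: the **outside** (rim) zone
is every section pixel within `rim_width` of the boundary by Euclidean
distance, the **inside** (core) is the remainder. ROIs are assigned to
the zone containing their centroid (`assign_zones()`). The default rim
width, `auto_rim_width()`, is twice the estimated median cell diameter
(`4·sqrt(median(area)/π)`), i.e. the one-to-two outermost cell layers;
because no principled universal width exists, `rim_width_sweep()` reports
the sensitivity of the enrichment to this choice.

`rim_enrichment()` follows difference-and-divide bookkeeping over per-ROI
summed intensities: `sum_total` and `sum_outside` are accumulated,
`sum_inside = sum_total − sum_outside` and
`n_inside = n_total − n_outside` exactly, zone means are sums over
counts, and the result is `mean_outside / mean_inside` with
`percent_brighter = 100·(ratio − 1)`. The ratio is invariant to a gain
but not to an offset, so a per-pixel background (median intensity outside
the section mask, `estimate_background()`) is subtracted as
`background · area` per ROI before summing.

## Condition summaries, positivity, growth, densitometry

`condition_summary()` reports both ROI-level and image-level statistics
(mean of per-image means), because pooling ROIs across images
pseudoreplicates; downstream statistics should use the image-level
values. Sample (n−1) standard deviations are used throughout.

`positive_fraction()` thresholds per-ROI mean intensities by Otsu
(default), a fixed value, or a two-component Gaussian mixture; the rule
and threshold are part of the result. The fixed rule is monotone
non-increasing in the threshold (tested), and the Otsu rule recovers a
30% positive fraction within ±0.03 on a clearly bimodal 1000-cell field.

`culture_areas()` quantifies phase-contrast images of dark cultures on a
bright background: Otsu split, compact body = largest component after
closing (area counted on the un-closed dark mask), total area = compact
plus every other dark particle of ≥ 10 px. The compact fraction is the
morphometric readout for cultures that shed outward-moving cells; 2D area
is used deliberately — sections and projections make volumes
unrecoverable, so area-based growth curves are the honest quantity.

`densitometry_ratio()` integrates lane profiles over annotated band
windows after baseline subtraction and divides by the loading-control
integral per lane. The default baseline is the **median profile value
over rows outside every annotated band window**: a rolling minimum, the
classical choice, is biased low on noisy profiles (it tracks the minima
of the noise), which inflates small-band ratios by several percent,
whereas the flanking median is unbiased for the flat background of a film
scan. A morphological-opening baseline (`baseline = "rolling_open"`)
remains available for sloping backgrounds. Band windows should span about
±4σ so the flanks reach true background.

## The synthetic-scene generator

`scene_spec()` defaults encode the study conditions the tests run under:
384×384 px frames; a 150 px section radius; nuclei of radius 6 ± 0.8 px
rendered as cosine-falloff profiles (peak 150 AU) so that
auto-thresholding is non-trivial, with additive overlap between
neighbours as under a point-spread function; placement by rejection
sampling with centers at least `0.8·(r_i + r_j)` apart (mild overlap, to
exercise the watershed) and reaching within 2 px of the section border
(edge nuclei are clipped by the section boundary, as in real
cryosections); background 10 AU, Poisson noise on the signal plus 5 AU
Gaussian read noise. The marker channel is a cell-intrinsic stain
confined to each cell's territory (the pixels it is relatively closest
to), with the per-cell profile normalized so that the territory mean
equals the cell's true level exactly — this makes "true marker level" a
well-defined measurable quantity and lets fold and enrichment recoveries
be compared against exact truths. The default rim enrichment factor is
1.33 (rim cells ~33% brighter than the core); a 4.3-fold 3D-over-2D
marker difference is expressed by scaling `marker_base_level` between a
spheroid and a monolayer scene; growth series and gels carry their own
specs with exact area and integral truths. A tear artifact (straight
cell-free cut) is available to verify that rim staining tracks only the
true border. Identical spec + seed reproduces every output byte.

What the generator does **not** emulate: real optics (measured PSFs,
3D light scattering, z-stacks), chromatic misregistration, autofluorescence
texture, irregular section outlines, or cell-shape variation beyond
radius jitter. Passing recoveries therefore demonstrate that the
implementation is correct and unbiased under a controlled, realistic
noise model — not that any particular biological image will be segmented
at the same fidelity.

## Numerical choices and degenerate inputs

Thresholds use 256 equal bins over the observed range; isodata stops at a
1e-9 relative fixed point (bounded at 200 iterations). A constant image
yields an empty foreground (threshold = max), an unchanged contrast
stretch with a notice, and a structureless verdict from the guard. Empty
label maps flow through every operation as empty tables or empty masks,
never errors, except where a quantity is undefined (empty rim or core
zone, vanished loading control, rim width that leaves no core) — those
raise errors naming the problem. Label TIFFs are written 16-bit and
promoted to 32-bit float beyond 65535 labels (exact below 2²³), never
silently truncated.

Two quantities deserve an explicit caveat. First, per-ROI mean
intensities measured on detected footprints carry a core bias: thresholds
keep the bright center of each cell, so measured means exceed the true
per-cell mean, and the bias differs between sparse and dense scenes
(≈ +12% vs ≈ +20% under default conditions). Ratios of such means across
conditions are therefore accurate only to roughly that differential
(observed ≈ +8% on the 4.3-fold experiment at default noise); the
zero-noise fold check instead evaluates the measurement-and-summary chain
on exact ground-truth ROIs, where it is exact by construction. Second,
the rim/core enrichment is insensitive to this bias (both zones share the
footprint geometry) but is sensitive to the rim-width choice, which is
why the sweep exists.

## Problem sizes in the tests

The suite validates operators on 16×16 oracle images (50 each), scenes of
60–300 cells at 256–560 px frames, ten seeds for segmentation recovery,
twenty seeds per factor for enrichment recovery, and three-day growth
series — sizes chosen so the whole suite runs in about a minute while
keeping Monte-Carlo error well inside the asserted tolerances.
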