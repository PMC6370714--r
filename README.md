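# spheroidseg

Image analysis for 3D tumor-spheroid cultures, in R.

When spheroids (for example MDA-MB-231 breast-cancer cultures) are
cryosectioned and imaged by confocal immunofluorescence, the cells of
interest sit densely packed inside a roughly circular section, often with a
brightly stained rim. A single global threshold on such an image finds
little more than the bright spheroid border; the cells in the core are
missed. `spheroidseg` implements a multistep segmentation routine that
handles this case — median denoising, a contrast stretch that saturates the
brightest (rim) pixels, automatic histogram thresholding, dilation,
distance-transform watershed splitting of touching cells, and a particle
size filter — together with the downstream quantification a spheroid study
needs:

* **per-ROI measurement** on the *raw* intensities (area, centroid,
  per-channel mean and sum), never on processed intermediates;
* **rim/core enrichment**: the section mask is split into an outer rim and
  an inner core at a configurable rim width, and the enrichment statistic
  is computed by difference-and-divide bookkeeping over per-ROI sums —
  `sum_inside = sum_total − sum_outside`, `n_inside = n_total − n_outside`,
  zone means are `sum/n`, and the headline number is
  `ratio = mean_outside / mean_inside` (reported also as
  `percent_brighter = 100·(ratio − 1)`);
* **marker-positive cell fractions** (Otsu, fixed, or two-component
  Gaussian-mixture thresholds on per-ROI means);
* **growth-area morphometry** of phase-contrast series: total culture area,
  the compact spheroid body (largest dark component), and the compact
  fraction `compact/total`;
* **band densitometry** for blots, normalized per lane to a loading
  control.

Because public spheroid ground truth is scarce, the package ships a
deterministic synthetic-scene generator (`scene_spec()`,
`simulate_spheroid_slice()`, `simulate_monolayer()`,
`simulate_growth_series()`, `simulate_gel()`) that renders cryosection-like
images with *exact* per-cell ground truth — positions, radii, rim/core
zone, true marker levels, positivity, section masks — so every stage of the
pipeline is validated against known answers.

## Worked example: rim enrichment on a synthetic slice

```r
library(spheroidseg)

sp  <- scene_spec(n_cells = 300, rim_enrichment_factor = 1.33, seed = 42)
sim <- simulate_spheroid_slice(sp)

mask <- spheroid_mask(sim$image, "DAPI")
lab  <- gate_rois(multistep_segment(get_channel(sim$image, "marker")), mask)
tab  <- region_properties(lab, sim$image)
tab  <- assign_zones(tab, rim_partition(mask, auto_rim_width(tab)))
bg   <- estimate_background(sim$image, mask, "marker")

rim_enrichment(tab, "marker", background = bg)
#> <rim_enrichment> channel marker
#>   outside: n = 63, mean ROI sum = 1.008e+04
#>   inside:  n = 213, mean ROI sum = 7295
#>   outside/inside ratio = 1.3812 (38.1% brighter at the rim)
```

The scene was generated with rim cells 33% brighter than core cells; the
pipeline — segmentation of the marker channel, gating of off-section ROIs,
automatic rim width (here 21.3 px, twice the estimated median cell
diameter), background subtraction (estimated 9.9 AU against a true 10) —
recovers 38.1% for this single image; across 20 seeds the estimate averages
about 33%. The region table itself is a tibble ready for any downstream
tooling:

```r
head(tab[, c("label", "area_px", "mean_marker", "zone")], 3)
#> # A tibble: 3 × 4
#>   label area_px mean_marker zone
#> 1     1     125        99.7 outside
#> 2     2      85       109.  outside
#> 3     3     110       108.  outside
```

`tidy()` turns enrichment results into one-row tibbles;
`plot_channel()`, `plot_growth_curve()` and `plot_rim_sweep()` give quick
ggplot2 views; `rim_width_sweep()` reports how the enrichment ratio depends
on the rim-width choice. An end-to-end run (simulate or read → segment →
gate → measure → partition → quantify, with CSV/TIFF/JSON outputs and full
parameter provenance) is `run_pipeline()`; a thin command-line wrapper
lives at `inst/scripts/run-pipeline.R`.

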