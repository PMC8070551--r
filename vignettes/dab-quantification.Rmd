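---
title: "Quantifying DAB-positive macrophage area in whole-slide IHC scans"
author: "dabquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DAB-positive macrophage area in whole-slide IHC scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dabquant)
```

## The problem

Immunohistochemistry with a DAB chromogen marks antigen-positive cells —
here liver macrophages stained for CD68 (all macrophages), CD80
(pro-inflammatory) or CD163 (anti-inflammatory) — as brown deposits on a
blue-purple hematoxylin counterstain. A whole-slide brightfield scan of
such a section is a gigapixel RGB raster; the quantity of interest is the
fraction of the tissue-section area covered by marker-positive staining,
per donor, split by the size of the stained region. dabquant implements
this quantification as a deterministic, tile-based pipeline with an
explicit robustness estimate, and ships a synthetic H-DAB tile generator
so that every stage is testable against known ground truth without access
to patient scans.

## The segmentation method

Each slide is processed as 1000 × 1000 px tiles at a fixed physical pixel
size (0.221 µm/px by default; dabquant never infers it from file
metadata). Per tile:

1. **Signal transform.** The RGB tile $I_0$ is collapsed to a
   single-channel chromogen signal $I_1$. The default `inv_red_plus_green`
   mode computes $I_1 = (255 - I_0(R)) + I_0(G)$ in wide integer
   arithmetic, saturated to $[0, 255]$.
2. **Smoothing.** $I_2$ is a Gaussian-filtered $I_1$ with $\sigma = 5$ px
   (kernel truncated at $4\sigma$, mirror-reflect borders, response
   rounded half-up and clipped to 8 bits). This suppresses pixel noise
   while preserving the edge structure of stained features.
3. **Binarization.** $I_3(x) = 1$ iff $I_2(x) \ge T$, with marker-preset
   base thresholds $T = 13$ (CD68), $18$ (CD80), $21$ (CD163). The
   presets were established with Yen's maximum-correlation threshold on
   reference tiles; `yen_threshold()` implements that criterion over the
   256-bin histogram (ties toward the lowest candidate) for data-driven
   use.
4. **Labeling and measurement.** Connected components of $I_3$
   (8-connectivity by default) are labeled in deterministic raster order
   and measured: area in µm² is pixel count × (pixel size)².
5. **Filter and clusters.** Regions with area $\le 10$ µm² are discarded
   (strict inequality: a region must exceed 10 µm² to count). Survivors
   are clustered by area: cluster 1 $(10, 300]$ µm² — single macrophages
   and small groups; cluster 2 $(300, 2000]$ µm² — larger groups;
   cluster 3 $(2000, \infty)$ µm² — unspecific staining, recorded but
   excluded from all downstream statistics. The half-open convention
   closes the 300 → 300.01 gap of two-decimal reporting: every retained
   area belongs to exactly one cluster.

Steps 3–5 run three times per tile, at $T$, $T_{\min} = T - 3$ and
$T_{\max} = T + 4$. The spread of the three results is the method's own
sensitivity to the threshold choice and becomes the donor-level error
bar; it is *not* a biological variance.

### Donor summaries and statistics

Per donor, segmented area is summed per cluster and per threshold across
all tiles and divided by the donor's tissue-section area (from
`estimate_tissue_mask()`: a pixel is glass background iff
$\min(R,G,B) \ge 240$; tissue is the complement — the slide scan is
transmitted-light, so bare glass is near-white). The base-threshold
fraction is the reported value; the min/max over the window give
`error_low`/`error_high`, so the base value always lies inside its own
interval. Group comparison is a one-way ANOVA of base-threshold fractions
per cluster, followed by all pairwise t-tests (Welch by default;
pooled-variance by flag) with Bonferroni correction
($p_{adj} = \min(1, m \, p)$), and the usual star legend at
0.05/0.01/0.001/0.0001 applied to the adjusted p.

## Design choices in the open points

**The transform and white glass.** Taken literally,
$(255-R)+G$ assigns the *maximum* signal (255) to white glass
($R=G=255$) and nearly maximal values to the counterstain, so with base
thresholds of 13–21 essentially every pixel of a raw tile passes. The
original workflow interposed a manual, visually-controlled contrast
adjustment that cannot be reproduced programmatically, and we cannot
determine which channel convention the production scripts ultimately
ran. dabquant therefore (a) implements the printed formula verbatim as
the default `inv_red_plus_green` mode, (b) exposes two alternatives —
`dual_inverted`, $(255-R)+(255-G)$, and `blue_deficit`, $255-B$, which
operationalizes the stated rationale that DAB brown is blue-poor — and
(c) refuses to guess: ground truth in the synthetic generator is always
defined with respect to the configured mode. `stretch_contrast()` is
provided as an automated, logged stand-in for the manual tonal
adjustment and is off by default.

**Tissue denominator.** How the "whole tissue section area" was measured
is not specified in the source method; the near-white rule above is our
choice (cutoff configurable). Normalizing to the full scanned raster
instead is available by passing that area to `summarize_donor()`
directly.

**Numerical conventions.** Binarization is inclusive ($\ge T$);
connectivity defaults to 8, matching common particle-analysis tools;
Gaussian borders reflect; rounding is half-up; region labels follow the
raster position of each region's first pixel, making CSVs reproducible
byte-for-byte. Regions touching tile borders are measured per tile with
no cross-tile stitching — the per-tile CSV design fragments features
that straddle tile seams, a documented bias of the tiling architecture.

## The synthetic tile generator

`generate_tile()` emulates the image classes the segmentation must
separate: near-white glass (default RGB 250/250/252), a counterstained
tissue ellipse covering ~85% of the tile (190/180/215), elliptical
chromogen blobs (axis ratio 1–2.5) with log-normally distributed areas,
optional very large smears (cluster-3 truth), and additive Gaussian
pixel noise (sd 5 by default), clipped last. Rasterized per-blob pixel
counts are the ground truth; expected clusters are computed with the
pipeline's own cluster map.

The generator's colors must be *separable* under the configured
transform: chromogen signal above $T + 40$, background and counterstain
below $T - 40$ (margin configurable). With the realistic DAB-brown
default (145/105/70) this holds for `blue_deficit` at $T = 100$, which is
therefore the default synthetic configuration; for `inv_red_plus_green` the
constraint is infeasible with near-white glass (see above), so synthetic
work under that mode requires deliberately non-histological colors. This
is a property of the printed formula, not of the generator.

What the generator does **not** emulate: stain texture and intensity
gradients within a cell, chromatic scanner artifacts (vignetting, focus
blur), tissue folds, and touching-but-distinct cells (touching blobs are
only produced on request via `allow_touching`). Passing recovery tests
on synthetic tiles therefore demonstrates the correctness of the
computational chain — transform, smoothing, thresholding, labeling,
measurement — not the biological validity of the presets on real tissue.

`generate_cohort()` extends this to multi-donor studies: per-group mean
blob densities (per mm² of tissue) for clusters 1 and 2, a between-donor
log-normal multiplier with fixed coefficient of variation, Poisson
per-tile counts, truncated log-normal areas. The defaults (cluster-1
density 200/mm², cluster-2 10/mm², CV 0.3, 4 tiles/donor) were chosen
once as a realistic liver-macrophage regime: a design-time power
calculation put one-way ANOVA power for a 3× density contrast at 5
donors/group near 99%, comfortably detectable, while donor variability
remains visibly biological. `simulate_cohort_fractions()` draws from
exactly the same sampling model but skips rasterization, which is what
makes 1,000-replicate calibration studies affordable; a test verifies
the rendered pipeline recovers the fast path's fractions on a small
cohort.

## Problem sizes used in the shipped checks

The package's own test suite and the reproduction script run entirely on
synthetic data at sizes chosen to exercise every code path at full
parameter defaults: oracle cross-checks on 1,000 random histograms and
hundreds of random masks (exhaustively on all 512 3 × 3 masks, both
connectivities); 200 random 250 px tiles for threshold-window
monotonicity; 50 clean 700 px tiles × 10 blobs for count/area/cluster
recovery (areas 50–250 µm², recovered within ±15%; smoothing blurs
edges, so exact areas are not expected); 1,000 fast-path cohorts for
null calibration and 200 for power. Whole-slide-scale inputs differ only
in tile count, which the pipeline processes independently per tile.

## Known limitations

- No color deconvolution (Ruifrok–Johnston); the method is a raw channel
  combination by design. Deconvolution-based stain separation would be
  the natural alternative but is out of scope.
- No nucleus counting or per-cell classification: areas, not cells.
- Tile-seam fragmentation (above) biases large-region counts upward and
  their areas downward near seams.
- The marker presets $T = 13/18/21$ derive from reference tiles that are
  not redistributable; they are fixed configuration, not reproducible
  outputs of this package.
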