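# dabquant

Tile-based quantification of DAB-positive macrophage area in whole-slide
brightfield immunohistochemistry (IHC) scans, with a synthetic H-DAB
image generator that makes the entire pipeline testable without patient
data.

## What it computes

IHC with a DAB chromogen marks antigen-positive cells (CD68/CD80/CD163
macrophage markers in liver sections) as brown deposits on a hematoxylin
counterstain. For each donor, dabquant reports the **normalized positive
area fraction**: total segmented marker-positive area divided by the
tissue-section area, split by region size:

- **cluster 1**, (10, 300] µm² — single macrophages and small groups;
- **cluster 2**, (300, 2000] µm² — larger macrophage groups;
- **cluster 3**, > 2000 µm² — unspecific staining, excluded from
  statistics.

Per 1000 × 1000 px tile (0.221 µm/px), the method runs:

1. chromogen signal transform `I1 = (255 − R) + G` (saturated 8-bit;
   alternative modes `dual_inverted` and `blue_deficit` are provided —
   see the methods vignette for why);
2. Gaussian smoothing, σ = 5 px → `I2`;
3. binarization `I3 = I2 ≥ T`, with marker presets T = 13 (CD68),
   18 (CD80), 21 (CD163), derived via Yen's maximum-correlation
   threshold (`yen_threshold()`);
4. connected-component labeling (8-connectivity, deterministic raster
   order);
5. area measurement, a strict > 10 µm² filter, and cluster assignment.

Each tile is segmented at T − 3, T, and T + 4; the spread across this
threshold window is reported as the donor-level error bar — the error of
the detection method itself. Donor groups are compared per cluster with
one-way ANOVA plus Bonferroni-corrected pairwise t-tests.

## Worked example

Generate a synthetic tile with known ground truth, segment it, and
summarize:

```r
library(dabquant)

spec   <- tile_spec(tile_size_px = 500, n_blobs = 6, seed = 42)
gen    <- generate_tile(spec)               # image + ground truth
params <- params_for_spec(spec)             # window −3/+4, sigma 5, clusters
result <- segment_tile(gen$image, params, tile_id = "demo")
tile_summary(result)
#> # A tibble: 3 × 4
#>   threshold cluster n_regions total_area_um2
#>       <int>   <int>     <int>          <dbl>
#> 1        97       1         6           805.
#> 2       100       1         6           790.
#> 3       104       1         6           770.
```

All 6 blobs are recovered at every threshold of the window, and the
segmented area shrinks monotonically as the threshold rises. Normalizing
to the tissue area measured on the same tile:

```r
tissue <- estimate_tissue_mask(gen$image)
tissue
#> <tissue_mask> 210401 tissue px, 10276.2 um^2 (84.2% of raster)
summarize_donor(result, tissue$tissue_area_um2, params, donor_id = "D01")
#>   donor_id cluster fraction_base error_low error_high
#> 1      D01       1       0.07688   0.07489    0.07837
#> 2      D01       2       0.00000   0.00000    0.00000
```

7.7% of the tissue area is marker-positive in cluster 1, with the
threshold-window interval [0.0749, 0.0784] around it; no cluster-2
regions exist on this tile. `compare_groups()` then takes such summaries
across donors, and `autoplot()` draws the per-donor bar chart with
window error bars. `run_segment()` / `run_full()` (or the thin CLI at
`inst/cli/dabquant.R`) drive the same steps over whole slides and donor
manifests, writing per-tile CSVs, overlay PNGs, summary tables and the
resolved configuration.

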