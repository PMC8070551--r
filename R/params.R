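#' Segmentation parameters and marker presets
#'
#' Bundles every tunable of the tile segmentation method. The marker presets
#' carry the base thresholds established for the three macrophage stains
#' (CD68: T = 13, CD80: T = 18, CD163: T = 21); the robustness window
#' spans from 3 greyscale values below to 4 above the base threshold, so
#' each tile is additionally segmented at T - 3 and T + 4 and the spread of
#' the results quantifies the method's threshold sensitivity.
#'
#' Transform modes for the chromogen signal (see [compute_signal()]):
#' `"inv_red_plus_green"` is `(255 - R) + G` saturated to 8 bits;
#' `"dual_inverted"` is `(255 - R) + (255 - G)` saturated; `"blue_deficit"`
#' is `255 - B`, exploiting the low blue component of DAB brown.
#'
#' @param marker one of `"CD68"`, `"CD80"`, `"CD163"`, or `NULL` when
#'   `base_threshold` is given explicitly.
#' @param base_threshold 8-bit base threshold T; overrides the preset.
#' @param window_below,window_above greyscale offsets defining
#'   T_min = T - window_below and T_max = T + window_above (defaults 3, 4).
#' @param sigma_px Gaussian smoothing width in pixels (default 5).
#' @param min_area_um2 strict minimum region area in um^2 (default 10):
#'   regions with area <= this are discarded.
#' @param cluster1_max_um2,cluster2_max_um2 upper bounds (inclusive) of
#'   area clusters 1 and 2 in um^2 (defaults 300, 2000). Cluster 1 holds
#'   single macrophages and small groups, cluster 2 larger groups,
#'   cluster 3 (> `cluster2_max_um2`) unspecific staining.
#' @param connectivity pixel connectivity for region labeling: 8 (default,
#'   diagonal neighbours merge) or 4.
#' @param transform_mode chromogen signal transform, see Details.
#' @return A `segmentation_params` list.
#' @examples
#' segmentation_params(marker = "CD68")
#' segmentation_params(base_threshold = 100, transform_mode = "blue_deficit")
#' @export
segmentation_params <- function(marker = NULL,
                                base_threshold = NULL,
                                window_below = 3,
                                window_above = 4,
                                sigma_px = 5,
                                min_area_um2 = 10,
                                cluster1_max_um2 = 300,
                                cluster2_max_um2 = 2000,
                                connectivity = 8,
                                transform_mode = c("inv_red_plus_green",
                                                   "dual_inverted",
                                                   "blue_deficit")) {
  transform_mode <- match.arg(transform_mode)
  presets <- c(CD68 = 13, CD80 = 18, CD163 = 21)
  if (is.null(base_threshold)) {
    if (is.null(marker) || !marker %in% names(presets)) {
      abort("give `base_threshold` or a known `marker` (CD68, CD80, CD163).")
    }
    base_threshold <- unname(presets[marker])
  }
  t <- base_threshold
  if (t - window_below < 0 || t + window_above > 255) {
    abort("threshold window must stay inside [0, 255].")
  }
  if (sigma_px < 0) abort("`sigma_px` must be >= 0.")
  if (!(min_area_um2 > 0 && min_area_um2 < cluster1_max_um2 &&
        cluster1_max_um2 < cluster2_max_um2)) {
    abort("need 0 < min_area_um2 < cluster1_max_um2 < cluster2_max_um2.")
  }
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  structure(
    list(marker = marker %||% NA_character_,
         base_threshold = as.integer(t),
         window_below = as.integer(window_below),
         window_above = as.integer(window_above),
         sigma_px = sigma_px,
         min_area_um2 = min_area_um2,
         cluster1_max_um2 = cluster1_max_um2,
         cluster2_max_um2 = cluster2_max_um2,
         connectivity = as.integer(connectivity),
         transform_mode = transform_mode),
    class = "segmentation_params"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.segmentation_params <- function(x, ...) {
  cat(sprintf(
    "<segmentation_params> marker=%s T=%d window=[-%d,+%d] sigma=%g px\n  min area > %g um^2, clusters (%g,%g] / (%g,%g] / (%g,Inf) um^2\n  connectivity=%d, transform=%s\n",
    x$marker, x$base_threshold, x$window_below, x$window_above, x$sigma_px,
    x$min_area_um2, x$min_area_um2, x$cluster1_max_um2, x$cluster1_max_um2,
    x$cluster2_max_um2, x$cluster2_max_um2, x$connectivity, x$transform_mode))
  invisible(x)
}

#' Thresholds of the robustness window
#'
#' @param params a [segmentation_params] object.
#' @return Named integer vector `c(t_min, t_base, t_max)`.
#' @export
window_thresholds <- function(params) {
  c(t_min = params$base_threshold - params$window_below,
    t_base = params$base_threshold,
    t_max = params$base_threshold + params$window_above)
}

#' Classify region areas into size clusters
#'
#' Applies the strict minimum-area filter and the half-open cluster map:
#' areas <= `min_area_um2` are discarded (`NA`); cluster 1 is
#' `(min_area_um2, cluster1_max_um2]`, cluster 2 is
#' `(cluster1_max_um2, cluster2_max_um2]`, cluster 3 is
#' `(cluster2_max_um2, Inf)`. The half-open convention closes the printed
#' 300 -> 300.01 reporting gap: every retained area belongs to exactly one
#' cluster.
#'
#' @param area_um2 numeric vector of region areas in um^2.
#' @param params a [segmentation_params] object.
#' @return Integer vector of cluster labels 1/2/3, `NA` for discarded areas.
#' @examples
#' p <- segmentation_params(marker = "CD68")
#' classify_area(c(9.99, 10, 10.01, 300, 300.01, 2000, 2000.01), p)
#' @export
classify_area <- function(area_um2, params) {
  dplyr::case_when(
    area_um2 <= params$min_area_um2 ~ NA_integer_,
    area_um2 <= params$cluster1_max_um2 ~ 1L,
    area_um2 <= params$cluster2_max_um2 ~ 2L,
    TRUE ~ 3L
  )
}
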