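#' Segment one tile at the three window thresholds
#'
#' Runs the full per-tile chain: chromogen signal transform, Gaussian
#' smoothing (both computed once), then binarization, connected-component
#' labeling, and region measurement/clustering at each of T - window_below,
#' T, and T + window_above. The spread of the three results quantifies the
#' sensitivity of the segmentation to the threshold choice and is reported
#' downstream as the donor-level error bar.
#'
#' @param tile an [rgb_image].
#' @param params a [segmentation_params] object.
#' @param tile_id identifier recorded in the result (default `"tile"`).
#' @return A `tile_result`: tibble with columns `tile_id`, `threshold`,
#'   `region_id`, `pixel_count`, `area_um2`, `cluster`, one row per
#'   retained region per threshold, plus attributes `thresholds` (the
#'   window), `params`, and `pixel_size_um`. Thresholds with no region
#'   contribute no rows but remain present in the `thresholds` attribute.
#' @examples
#' spec <- tile_spec(tile_size_px = 200, n_blobs = 2, seed = 1)
#' tile <- generate_tile(spec)$image
#' p <- segmentation_params(base_threshold = 100, transform_mode = "blue_deficit")
#' segment_tile(tile, p)
#' @export
segment_tile <- function(tile, params, tile_id = "tile") {
  stopifnot(is_rgb_image(tile), inherits(params, "segmentation_params"))
  sig <- compute_signal(tile, params$transform_mode)
  sm <- gaussian_smooth(sig, params$sigma_px)
  ps <- pixel_size(tile)
  thr <- window_thresholds(params)
  regions <- purrr::map(thr, function(t) {
    lab <- label_connected(binarize(sm, t), params$connectivity)
    measure_filter_cluster(lab, ps, params, t)
  })
  out <- dplyr::bind_rows(regions)
  out <- dplyr::bind_cols(tibble(tile_id = rep(tile_id, nrow(out))), out)
  out <- out[, c("tile_id", "threshold", "region_id", "pixel_count",
                 "area_um2", "cluster")]
  new_tile_result(out, thresholds = thr, params = params, pixel_size_um = ps)
}

new_tile_result <- function(df, thresholds, params, pixel_size_um) {
  structure(as_tibble(df),
            thresholds = thresholds, params = params,
            pixel_size_um = pixel_size_um,
            class = c("tile_result", class(as_tibble(df))))
}

#' @export
print.tile_result <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf("<tile_result> thresholds %d/%d/%d, %d region rows\n",
              thr[1], thr[2], thr[3], nrow(x)))
  NextMethod()
}

#' Region count and area per threshold and cluster
#'
#' @param result a `tile_result` (or row-bound set of them).
#' @return Tibble with `threshold`, `cluster`, `n_regions`,
#'   `total_area_um2`.
#' @export
tile_summary <- function(result) {
  result |>
    as_tibble() |>
    dplyr::group_by(.data$threshold, .data$cluster) |>
    dplyr::summarise(n_regions = dplyr::n(),
                     total_area_um2 = sum(.data$area_um2),
                     .groups = "drop")
}

#' Overlay segmented regions on the original tile
#'
#' Visual QC output: pixels of retained regions at the chosen threshold are
#' recolored by cluster — green for cluster 1 (single macrophages / small
#' groups), red for cluster 2 (larger groups), blue for cluster 3
#' (unspecific staining). All other pixels are untouched.
#'
#' @param tile the original [rgb_image].
#' @param result the `tile_result` from [segment_tile()] on that tile.
#' @param threshold which of the three window thresholds to display
#'   (default: the base threshold).
#' @return An [rgb_image] copy with regions recolored.
#' @export
render_overlay <- function(tile, result, threshold = NULL) {
  stopifnot(is_rgb_image(tile), inherits(result, "tile_result"))
  thr <- attr(result, "thresholds")
  threshold <- threshold %||% thr[["t_base"]]
  if (!threshold %in% thr) {
    abort(sprintf("threshold %s is not in the result window (%s).",
                  threshold, paste(thr, collapse = "/")))
  }
  params <- attr(result, "params")
  sm <- gaussian_smooth(compute_signal(tile, params$transform_mode),
                        params$sigma_px)
  lab <- label_connected(binarize(sm, threshold), params$connectivity)
  rows <- result[result$threshold == threshold, ]
  px <- unclass(tile)
  colors <- list(`1` = c(0L, 255L, 0L), `2` = c(255L, 0L, 0L),
                 `3` = c(0L, 0L, 255L))
  for (cl in unique(rows$cluster)) {
    sel <- unclass(lab) %in% rows$region_id[rows$cluster == cl]
    dim(sel) <- dim(lab)
    col <- colors[[as.character(cl)]]
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[sel] <- col[ch]
      px[, , ch] <- plane
    }
  }
  rgb_image(px, pixel_size_um = pixel_size(tile))
}
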