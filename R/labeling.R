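#' Label connected feature regions (Step 5)
#'
#' Finds maximal connected components of foreground pixels under 4- or
#' 8-connectivity. Labels are assigned 1..n in the raster order
#' (left-to-right, top-to-bottom) of each region's first pixel, so the
#' numbering in exported CSVs is deterministic.
#'
#' @param mask a `binary_mask` (from [binarize()]) or a plain 0/1 matrix.
#' @param connectivity 4 or 8 (default 8: diagonally touching pixels merge,
#'   matching common particle-analysis behaviour).
#' @return A `label_image`: integer matrix, 0 = background, with attributes
#'   `n_regions` and `pixel_size_um`.
#' @examples
#' m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[2, 2] <- 1L
#' attr(label_connected(m, 8), "n_regions")  # 1
#' attr(label_connected(m, 4), "n_regions")  # 2
#' @export
label_connected <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  ps <- attr(mask, "pixel_size_um")
  m <- unclass(mask)
  storage.mode(m) <- "integer"
  lab <- .label_connected_cpp(m, as.integer(connectivity))
  structure(lab, n_regions = attr(lab, "n_regions"), pixel_size_um = ps,
            class = "label_image")
}

#' Measure, filter, and cluster labeled regions
#'
#' Converts a label image into the per-region feature table: pixel count,
#' physical area (`pixel_count * pixel_size_um^2`), and size-cluster label.
#' Regions at or below the minimum area are discarded; survivors are
#' assigned cluster 1, 2, or 3 by [classify_area()].
#'
#' @param labels a `label_image` from [label_connected()].
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @param params a [segmentation_params] object.
#' @param threshold_used the 8-bit threshold that produced the mask, stored
#'   alongside each region.
#' @return Tibble with columns `region_id`, `pixel_count`, `area_um2`,
#'   `cluster`, `threshold` — one row per retained region, ordered by
#'   `region_id`.
#' @export
measure_filter_cluster <- function(labels, pixel_size_um, params,
                                   threshold_used) {
  stopifnot(pixel_size_um > 0)
  n <- attr(labels, "n_regions")
  empty <- tibble(region_id = integer(), pixel_count = integer(),
                  area_um2 = numeric(), cluster = integer(),
                  threshold = integer())
  if (n == 0) return(empty)
  counts <- tabulate(unclass(labels)[unclass(labels) > 0L], nbins = n)
  area <- counts * pixel_size_um^2
  cl <- classify_area(area, params)
  keep <- !is.na(cl)
  if (!any(keep)) return(empty)
  tibble(
    region_id = seq_len(n)[keep],
    pixel_count = counts[keep],
    area_um2 = area[keep],
    cluster = cl[keep],
    threshold = as.integer(threshold_used)
  )
}
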