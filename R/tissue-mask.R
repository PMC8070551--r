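#' Estimate the tissue mask of a brightfield tile or slide
#'
#' In transmitted-light scans, bare glass is near-white in every channel
#' while counterstained tissue absorbs at least one channel. A pixel is
#' classified as background iff `min(R, G, B) >= background_min_intensity`;
#' tissue is the complement. The tissue area in um^2 is the tissue pixel
#' count times the squared pixel size, exactly. This area is the
#' denominator when segmented macrophage area is normalized per donor.
#'
#' @param img an [rgb_image].
#' @param background_min_intensity 8-bit cutoff (default 240): a pixel at or
#'   above this value in all three channels counts as glass background.
#' @return A `tissue_mask`: list with `mask` (H x W integer matrix, 1 =
#'   tissue), `tissue_px` (count), and `tissue_area_um2`.
#' @examples
#' img <- rgb_image(array(255L, c(10, 10, 3)))
#' estimate_tissue_mask(img)$tissue_area_um2  # 0: all glass
#' @export
estimate_tissue_mask <- function(img, background_min_intensity = 240) {
  stopifnot(is_rgb_image(img))
  px <- unclass(img)
  min_ch <- pmin(px[, , 1], px[, , 2], px[, , 3])
  mask <- (min_ch < background_min_intensity) * 1L
  dim(mask) <- dim(px)[1:2]
  n <- sum(mask)
  structure(
    list(mask = mask, tissue_px = n,
         tissue_area_um2 = n * pixel_size(img)^2),
    class = "tissue_mask"
  )
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d tissue px, %.1f um^2 (%.1f%% of raster)\n",
              x$tissue_px, x$tissue_area_um2,
              100 * x$tissue_px / length(x$mask)))
  invisible(x)
}
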