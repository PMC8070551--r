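#' Split an image into fixed-size tiles
#'
#' Cuts the image into a row-major grid of `tile_size_px` x `tile_size_px`
#' tiles, the processing unit for whole-slide scans. Edge tiles keep their
#' natural (smaller) size; padding would inflate apparent background area.
#' The tiles partition the image: [reassemble_tiles()] reproduces the input
#' bit-exactly.
#'
#' @param img an [rgb_image].
#' @param tile_size_px tile edge length in pixels (default 1000).
#' @return A tibble with one row per tile: `row`, `col` (0-based grid
#'   indices), `origin_y_px`, `origin_x_px` (0-based pixel offsets of the
#'   tile's top-left corner), `height_px`, `width_px`, `tile_id`, and a
#'   list-column `tile` of [rgb_image]s.
#' @examples
#' img <- rgb_image(array(sample(0:255, 60 * 40 * 3, TRUE), c(60, 40, 3)))
#' tiles <- split_into_tiles(img, tile_size_px = 25)
#' nrow(tiles)  # 3 x 2 grid
#' @export
split_into_tiles <- function(img, tile_size_px = 1000) {
  stopifnot(is_rgb_image(img))
  if (tile_size_px < 1) abort("`tile_size_px` must be >= 1.")
  h <- dim(img)[1]; w <- dim(img)[2]
  n_rows <- ceiling(h / tile_size_px)
  n_cols <- ceiling(w / tile_size_px)
  grid <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  grid <- grid[, c("row", "col")] # row-major order
  ps <- pixel_size(img)
  tiles <- purrr::pmap(grid, function(row, col) {
    y0 <- row * tile_size_px
    x0 <- col * tile_size_px
    ys <- (y0 + 1):min(y0 + tile_size_px, h)
    xs <- (x0 + 1):min(x0 + tile_size_px, w)
    rgb_image(unclass(img)[ys, xs, , drop = FALSE], pixel_size_um = ps)
  })
  tibble(
    row = as.integer(grid$row),
    col = as.integer(grid$col),
    origin_y_px = as.integer(grid$row * tile_size_px),
    origin_x_px = as.integer(grid$col * tile_size_px),
    height_px = purrr::map_int(tiles, ~ dim(.x)[1]),
    width_px = purrr::map_int(tiles, ~ dim(.x)[2]),
    tile_id = sprintf("r%d_c%d", grid$row, grid$col),
    tile = tiles
  )
}

#' Reassemble tiles into the original image
#'
#' Inverse of [split_into_tiles()].
#'
#' @param tiles tibble as returned by [split_into_tiles()].
#' @return The reconstructed [rgb_image].
#' @export
reassemble_tiles <- function(tiles) {
  h <- max(tiles$origin_y_px + tiles$height_px)
  w <- max(tiles$origin_x_px + tiles$width_px)
  out <- array(0L, c(h, w, 3))
  for (i in seq_len(nrow(tiles))) {
    ys <- tiles$origin_y_px[i] + seq_len(tiles$height_px[i])
    xs <- tiles$origin_x_px[i] + seq_len(tiles$width_px[i])
    out[ys, xs, ] <- unclass(tiles$tile[[i]])
  }
  rgb_image(out, pixel_size_um = pixel_size(tiles$tile[[1]]))
}

#' Write tiles to disk
#'
#' Writes each tile as `<slide_id>_r<row>_c<col>.tif` under `dir`.
#'
#' @param tiles tibble from [split_into_tiles()].
#' @param dir output directory (created if missing).
#' @param slide_id slide identifier used as the filename stem.
#' @return The tibble with a `path` column added, invisibly.
#' @export
write_tiles <- function(tiles, dir, slide_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%s.tif", slide_id, tiles$tile_id))
  purrr::walk2(tiles$tile, paths, write_rgb_image)
  invisible(dplyr::mutate(tiles, path = paths))
}
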