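#' 8-bit RGB image with a physical pixel size
#'
#' An `rgb_image` is an `H x W x 3` integer array of 8-bit channel values
#' with a `pixel_size_um` attribute giving the physical edge length of one
#' pixel in micrometres. All raster-level functions in dabquant consume and
#' produce this class. The default pixel size of 0.221 um matches a 20x
#' brightfield slide scan.
#'
#' @param pixels numeric or integer `H x W x 3` array with values in 0..255.
#' @param pixel_size_um physical pixel edge length in micrometres (> 0).
#' @return An `rgb_image` object.
#' @examples
#' img <- rgb_image(array(128L, c(4, 4, 3)))
#' dim(img)
#' pixel_size(img)
#' @export
rgb_image <- function(pixels, pixel_size_um = 0.221) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    abort("`pixels` must be an H x W x 3 array.", class = "dabquant_format_error")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("channel values must lie in [0, 255] with no NA.",
          class = "dabquant_format_error")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.",
          class = "dabquant_format_error")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, pixel_size_um = pixel_size_um, class = "rgb_image")
}

#' @rdname rgb_image
#' @param x an `rgb_image`.
#' @export
pixel_size <- function(x) attr(x, "pixel_size_um")

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px, 8-bit RGB, %.4g um/px\n",
              d[1], d[2], pixel_size(x)))
  invisible(x)
}

is_rgb_image <- function(x) inherits(x, "rgb_image")

#' Read an 8-bit RGB image from TIFF or PNG
#'
#' The physical pixel size is supplied by the caller, never inferred from
#' file metadata. Grayscale input is rejected; RGBA input has its alpha
#' channel dropped with a warning (`strict = FALSE`, the default) or is
#' rejected (`strict = TRUE`). TIFF files with more than 8 bits per sample
#' are rejected.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @param strict reject RGBA instead of dropping alpha.
#' @return An [rgb_image].
#' @export
read_rgb_image <- function(path, pixel_size_um = 0.221, strict = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "dabquant_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, payload = FALSE)
    bps <- info$bits.per.sample
    if (!is.null(bps) && any(bps > 8)) {
      abort(sprintf("%s: bits per sample is %d, expected 8.", path, max(bps)),
            class = "dabquant_format_error")
    }
    raw <- tiff::readTIFF(path)
  } else if (ext == "png") {
    raw <- png::readPNG(path)
  } else {
    abort(sprintf("unsupported image format: .%s", ext),
          class = "dabquant_format_error")
  }
  if (length(dim(raw)) != 3) {
    abort(sprintf("%s: image has 1 channel, expected 3 (RGB).", path),
          class = "dabquant_format_error")
  }
  nch <- dim(raw)[3]
  if (nch == 4) {
    if (strict) {
      abort(sprintf("%s: image has an alpha channel (RGBA) and strict mode is on.",
                    path), class = "dabquant_format_error")
    }
    warn(sprintf("%s: dropping alpha channel.", path))
    raw <- raw[, , 1:3, drop = FALSE]
  } else if (nch != 3) {
    abort(sprintf("%s: image has %d channels, expected 3 (RGB).", path, nch),
          class = "dabquant_format_error")
  }
  rgb_image(round(raw * 255), pixel_size_um = pixel_size_um)
}

#' Write an 8-bit RGB image to TIFF or PNG
#'
#' Lossless; [read_rgb_image()] of the written file reproduces the pixels
#' bit-exactly.
#'
#' @param img an [rgb_image].
#' @param path destination path ending in `.tif`, `.tiff`, or `.png`.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  stopifnot(is_rgb_image(img))
  ext <- tolower(tools::file_ext(path))
  scaled <- unclass(img) / 255
  attributes(scaled) <- list(dim = dim(img))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 8L, compression = "none")
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else {
    abort(sprintf("unsupported image format: .%s", ext),
          class = "dabquant_format_error")
  }
  invisible(path)
}
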