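#' Linear percentile contrast stretch
#'
#' Automated stand-in for the manual tonal-value spreading applied during
#' slide pre-processing: each channel is rescaled linearly so that its
#' `low`/`high` percentiles map to 0/255, then clipped to [0, 255]. A
#' channel whose low and high percentiles coincide (constant or
#' near-constant channel) is returned unchanged with a warning. Optional
#' stage: with `enabled = FALSE` the input is returned untouched.
#'
#' @param img an [rgb_image].
#' @param low,high percentiles in [0, 100], `low < high`.
#' @param enabled if `FALSE`, identity.
#' @return An [rgb_image] of the same size.
#' @examples
#' img <- rgb_image(array(rep(c(50L, 200L), each = 24), c(4, 4, 3)))
#' range(stretch_contrast(img))  # 0 255
#' @export
stretch_contrast <- function(img, low = 1, high = 99, enabled = TRUE) {
  stopifnot(is_rgb_image(img))
  if (!enabled) return(img)
  if (!(low >= 0 && low < high && high <= 100)) {
    abort("need 0 <= low < high <= 100.")
  }
  px <- unclass(img)
  out <- px
  for (ch in 1:3) {
    v <- px[, , ch]
    q <- stats::quantile(v, c(low, high) / 100, names = FALSE, type = 7)
    if (diff(q) <= 0) {
      warn(sprintf("channel %d is degenerate (percentiles coincide at %g); left unchanged.",
                   ch, q[1]))
      next
    }
    out[, , ch] <- pmin(pmax(round((v - q[1]) * 255 / (q[2] - q[1])), 0), 255)
  }
  rgb_image(out, pixel_size_um = pixel_size(img))
}
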