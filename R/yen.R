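#' Yen maximum-correlation threshold
#'
#' Automatic bilevel threshold maximizing Yen's maximum-correlation
#' criterion over the 256-bin greyscale histogram. For each candidate
#' threshold t, pixels split into background (value < t) and foreground
#' (value >= t), consistent with the inclusive rule of [binarize()]. With
#' normalized histogram p and cumulative P(t) = sum(p[v < t]), the
#' criterion is
#'
#'   TC(t) = -log(G1 G2) + 2 log(P (1 - P)),
#'
#' where G1 = sum of p^2 over the background class and G2 over the
#' foreground class. All candidates with both classes non-empty are
#' scanned; ties break toward the lowest threshold; a constant image
#' returns its constant value.
#'
#' This is how the base thresholds of the marker presets were derived on
#' reference tiles; at run time it also provides a data-driven threshold
#' for synthetic or re-stained material.
#'
#' @param signal a `signal_image` or any integer matrix/vector with values
#'   in 0..255.
#' @return A single integer threshold in 0..255.
#' @examples
#' v <- matrix(c(rep(10L, 50), rep(200L, 50)), 10)
#' yen_threshold(v)
#' @export
yen_threshold <- function(signal) {
  v <- as.integer(unclass(signal))
  if (length(v) == 0) abort("empty image.")
  if (min(v) < 0 || max(v) > 255) abort("values must lie in 0..255.")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  if (sum(p > 0) == 1L) return(which(p > 0) - 1L) # constant image
  p2 <- p^2
  # P(t), G1(t): background class {v < t} for candidate thresholds t = 1..255
  P <- cumsum(p)[1:255]    # P[t] = Pr(v <= t-1) = Pr(v < t)
  G1 <- cumsum(p2)[1:255]
  G2 <- sum(p2) - G1
  valid <- P > 0 & P < 1 & G1 > 0 & G2 > 0
  crit <- rep(-Inf, 255)
  crit[valid] <- -log(G1[valid] * G2[valid]) +
    2 * log(P[valid] * (1 - P[valid]))
  which.max(crit) # which.max returns first (lowest t) on ties; t = index
}
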