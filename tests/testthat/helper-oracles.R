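# Independent reference implementations used to check the package's
# primitives. Deliberately naive: BFS flood fill, per-candidate histogram
# scans, direct 2-D convolution sums.

# Flood-fill connected-component labeling; labels in raster order of each
# component's first pixel.
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] == 1 && lab[r, c] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r, c)); lab[r, c] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nbr))) {
          rr <- p[1] + nbr[k, 1]; cc <- p[2] + nbr[k, 2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] == 1 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  attr(lab, "n_regions") <- nxt
  lab
}

# Yen threshold by per-candidate recomputation from raw pixel values:
# for every t, class sums are rebuilt from scratch.
yen_oracle <- function(values) {
  v <- as.integer(values)
  if (length(unique(v)) == 1) return(unique(v))
  n <- length(v)
  best_t <- NA_integer_; best_crit <- -Inf
  for (t in 1:255) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    p_lo <- tabulate(lo + 1L, 256L) / n
    p_hi <- tabulate(hi + 1L, 256L) / n
    P <- length(lo) / n
    G1 <- sum(p_lo^2); G2 <- sum(p_hi^2)
    crit <- -log(G1 * G2) + 2 * log(P * (1 - P))
    if (crit > best_crit + 1e-12) { best_crit <- crit; best_t <- t }
  }
  best_t
}

# direct (non-separable) Gaussian convolution with reflect borders
gaussian_oracle <- function(x, sigma, truncate = 4) {
  radius <- max(1, floor(truncate * sigma + 0.5))
  i <- -radius:radius
  k1 <- exp(-0.5 * i^2 / sigma^2); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  reflect <- function(i, n) {
    if (n == 1) return(1L)
    per <- 2 * (n - 1)
    i <- ((i - 1) %% per + per) %% per
    ifelse(i < n, i + 1L, per - i + 1L)
  }
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rows <- reflect(r + i, nr); cols <- reflect(c + i, nc)
    out[r, c] <- sum(k2 * x[rows, cols])
  }
  out
}

# random binary mask with tunable foreground probability
random_mask <- function(nr, nc, p = 0.4) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}

# small random rgb_image fixture
random_rgb <- function(h = 20, w = 20, pixel_size_um = 0.221) {
  rgb_image(array(sample(0:255, h * w * 3, TRUE), c(h, w, 3)),
            pixel_size_um = pixel_size_um)
}

# canonicalize a labeling: map labels to raster-first-pixel order so two
# labelings can be compared as partitions
canonical_labels <- function(lab) {
  v <- as.integer(t(lab)) # row-major order
  remap <- integer(max(v, 1L))
  nxt <- 0L
  for (x in v) {
    if (x > 0 && remap[x] == 0L) { nxt <- nxt + 1L; remap[x] <- nxt }
  }
  out <- ifelse(v > 0, remap[pmax(v, 1L)], 0L)
  matrix(out, nrow(lab), ncol(lab), byrow = TRUE)
}

# ground-truth fractions of the cohort draw generate_cohort() rasterizes
cohort_fractions_for_test <- function(spec) {
  dabquant:::cohort_fractions(dabquant:::draw_cohort(spec))
}

# build signal_image objects directly for stage-level unit tests
signal_image_for_test <- function(v, stage = "raw_signal") {
  storage.mode(v) <- "integer"
  structure(v, stage = stage, pixel_size_um = 0.221, class = "signal_image")
}
smoothed_for_test <- function(v) signal_image_for_test(v, "smoothed")

default_synth_params <- function(...) {
  segmentation_params(base_threshold = 100, transform_mode = "blue_deficit",
                      ...)
}
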