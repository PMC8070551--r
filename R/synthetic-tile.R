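#' Specification of a synthetic H-DAB tile
#'
#' Describes one synthetic brightfield IHC tile: near-white glass
#' background, a bluish counterstained tissue region, elliptical
#' chromogen-positive blobs with controlled areas, optional very large
#' unspecific smears, and additive Gaussian pixel noise. Ground truth
#' (per-blob rasterized areas and expected clusters) is recorded at
#' generation, so every pipeline stage can be checked without real scans.
#'
#' Colors must be separable under the configured transform: the chromogen
#' signal must exceed `base_threshold + margin` and background and
#' counterstain signals fall below `base_threshold - margin`. The defaults
#' (DAB-brown chromogen, `blue_deficit` transform, T = 100) satisfy this
#' with the default margin of 40. For the `inv_red_plus_green` transform the
#' near-white defaults are infeasible — that formula maps white glass to
#' maximal signal — so callers must then supply a low-R/low-G chromogen
#' and a high-R background (non-histological colors).
#'
#' @param tile_size_px tile edge length in pixels (default 1000).
#' @param pixel_size_um physical pixel size (default 0.221).
#' @param background_color,counterstain_color,chromogen_color RGB triples.
#' @param n_blobs number of chromogen blobs (ignored when `blob_areas_um2`
#'   is given).
#' @param blob_area_meanlog,blob_area_sdlog log-normal parameters of blob
#'   area in um^2.
#' @param blob_area_range truncation range of sampled blob areas in um^2.
#' @param blob_areas_um2 optional explicit vector of target blob areas,
#'   bypassing the log-normal draw.
#' @param n_smears number of very large unspecific regions (area sampled
#'   from `smear_area_range`, landing in cluster 3).
#' @param smear_area_range area range of smears in um^2.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (8-bit greyscale units).
#' @param tissue_fraction target fraction of the tile covered by tissue.
#' @param axis_ratio_range ellipse major/minor axis ratio range.
#' @param min_gap_px minimum gap between blob ellipse bounding radii, so
#'   smoothing cannot merge neighbours (default 15).
#' @param allow_touching drop the blob overlap check (deliberately merged
#'   groups).
#' @param transform_mode,base_threshold,margin separability contract used
#'   to validate the colors (see Details).
#' @param seed RNG seed making the tile reproducible.
#' @return A `tile_spec` list.
#' @export
tile_spec <- function(tile_size_px = 1000,
                      pixel_size_um = 0.221,
                      background_color = c(250, 250, 252),
                      counterstain_color = c(190, 180, 215),
                      chromogen_color = c(145, 105, 70),
                      n_blobs = 10,
                      blob_area_meanlog = log(100),
                      blob_area_sdlog = 0.5,
                      blob_area_range = c(15, 295),
                      blob_areas_um2 = NULL,
                      n_smears = 0,
                      smear_area_range = c(2500, 6000),
                      noise_sd = 5,
                      tissue_fraction = 0.85,
                      axis_ratio_range = c(1, 2.5),
                      min_gap_px = 15,
                      allow_touching = FALSE,
                      transform_mode = "blue_deficit",
                      base_threshold = 100,
                      margin = 40,
                      seed = 1L) {
  check_rgb <- function(x, nm) {
    if (length(x) != 3 || any(x < 0 | x > 255)) {
      abort(sprintf("`%s` must be an RGB triple in 0..255.", nm))
    }
  }
  check_rgb(background_color, "background_color")
  check_rgb(counterstain_color, "counterstain_color")
  check_rgb(chromogen_color, "chromogen_color")
  sig <- function(col) {
    as.integer(compute_signal(rgb_image(array(as.integer(col), c(1, 1, 3)),
                                        pixel_size_um), transform_mode))
  }
  if (sig(chromogen_color) <= base_threshold + margin) {
    abort(sprintf(
      "chromogen signal %d under %s does not exceed T + margin = %d.",
      sig(chromogen_color), transform_mode, base_threshold + margin))
  }
  for (nm in c("background_color", "counterstain_color")) {
    s <- sig(get(nm))
    if (s >= base_threshold - margin) {
      abort(sprintf("%s signal %d under %s is not below T - margin = %d.",
                    nm, s, transform_mode, base_threshold - margin))
    }
  }
  structure(
    list(tile_size_px = as.integer(tile_size_px),
         pixel_size_um = pixel_size_um,
         background_color = as.integer(background_color),
         counterstain_color = as.integer(counterstain_color),
         chromogen_color = as.integer(chromogen_color),
         n_blobs = as.integer(n_blobs),
         blob_area_meanlog = blob_area_meanlog,
         blob_area_sdlog = blob_area_sdlog,
         blob_area_range = blob_area_range,
         blob_areas_um2 = blob_areas_um2,
         n_smears = as.integer(n_smears),
         smear_area_range = smear_area_range,
         noise_sd = noise_sd,
         tissue_fraction = tissue_fraction,
         axis_ratio_range = axis_ratio_range,
         min_gap_px = min_gap_px,
         allow_touching = allow_touching,
         transform_mode = transform_mode,
         base_threshold = as.integer(base_threshold),
         margin = margin,
         seed = as.integer(seed)),
    class = "tile_spec"
  )
}

#' Segmentation parameters matching a tile spec
#'
#' Convenience constructor: the window, smoothing, and cluster defaults
#' with the spec's transform mode and base threshold.
#'
#' @param spec a [tile_spec].
#' @param ... overrides passed to [segmentation_params()].
#' @export
params_for_spec <- function(spec, ...) {
  segmentation_params(base_threshold = spec$base_threshold,
                      transform_mode = spec$transform_mode, ...)
}

# evaluate code under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic per-unit sub-seed from a root seed and a counter
derive_seed <- function(root, counter) {
  as.integer((as.numeric(root) * 1000003 + counter * 7919) %% 2147483629)
}

#' Generate a synthetic H-DAB tile with ground truth
#'
#' Deterministic for a fixed spec (including its seed). The tissue region
#' is a centered ellipse scaled to the requested coverage; blobs are
#' ellipses with randomized eccentricity and orientation whose rasterized
#' pixel counts are recorded as ground truth; smears are large ellipses
#' landing in cluster 3; Gaussian noise is added last and clipped to
#' 8 bits.
#'
#' @param spec a [tile_spec].
#' @return List with `image` (an [rgb_image]), `truth` (tibble: `blob_id`,
#'   `kind` ("blob"/"smear"), `center_y`, `center_x`, `requested_area_um2`,
#'   `pixel_count`, `area_um2`, `expected_cluster`), and `tissue_px`
#'   (ground-truth tissue pixel count).
#' @export
generate_tile <- function(spec) {
  stopifnot(inherits(spec, "tile_spec"))
  with_seed(spec$seed, generate_tile_impl(spec))
}

generate_tile_impl <- function(spec) {
  n <- spec$tile_size_px
  ps <- spec$pixel_size_um

  # tissue: centered ellipse scaled so its clipped area ~ tissue_fraction
  s <- sqrt(4 * spec$tissue_fraction / pi)
  A <- n / 2 * s; B <- n / 2 * s
  cy <- n / 2 + 0.5; cx <- n / 2 + 0.5
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  tissue <- ((yy - cy) / B)^2 + ((xx - cx) / A)^2 <= 1

  px <- array(0L, c(n, n, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$background_color[ch], n, n)
    plane[tissue] <- spec$counterstain_color[ch]
    px[, , ch] <- plane
  }

  areas <- spec$blob_areas_um2
  if (is.null(areas) && spec$n_blobs > 0) {
    areas <- numeric(spec$n_blobs)
    for (i in seq_len(spec$n_blobs)) {
      for (try in 1:1000) {
        a <- rlnorm(1, spec$blob_area_meanlog, spec$blob_area_sdlog)
        if (a >= spec$blob_area_range[1] && a <= spec$blob_area_range[2]) {
          areas[i] <- a; break
        }
      }
      if (areas[i] == 0) {
        abort("could not sample a blob area inside `blob_area_range`.",
              class = "dabquant_generation_error")
      }
    }
  }
  areas <- areas %||% numeric(0)
  smear_areas <- if (spec$n_smears > 0) {
    runif(spec$n_smears, spec$smear_area_range[1], spec$smear_area_range[2])
  } else numeric(0)

  all_areas <- c(areas, smear_areas)
  kinds <- c(rep("blob", length(areas)), rep("smear", length(smear_areas)))
  placed <- list() # (cy, cx, bounding radius)
  truth <- vector("list", length(all_areas))

  for (i in seq_along(all_areas)) {
    apx <- all_areas[i] / ps^2
    q <- runif(1, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
    a_ax <- sqrt(apx * q / pi) # semi-major in px
    b_ax <- a_ax / q
    theta <- runif(1, 0, pi)
    if (2 * (a_ax + 3) >= n || a_ax + 4 >= min(A, B)) {
      abort(sprintf(
        "region %d (%.0f um^2) does not fit the %d px tissue region.",
        i, all_areas[i], n),
        class = "dabquant_generation_error")
    }
    ok <- FALSE
    for (try in 1:500) {
      by <- runif(1, a_ax + 3, n - a_ax - 3)
      bx <- runif(1, a_ax + 3, n - a_ax - 3)
      # center well inside the tissue ellipse
      if (((by - cy) / (B - a_ax - 3))^2 + ((bx - cx) / (A - a_ax - 3))^2 > 1) next
      clear <- TRUE
      if (!spec$allow_touching) {
        for (p in placed) {
          if ((by - p[1])^2 + (bx - p[2])^2 <
              (a_ax + p[3] + spec$min_gap_px)^2) { clear <- FALSE; break }
        }
      }
      if (clear) { ok <- TRUE; break }
    }
    if (!ok) {
      abort(sprintf("could not place region %d of %d: tissue too crowded for the spec.",
                    i, length(all_areas)),
            class = "dabquant_generation_error")
    }
    placed[[length(placed) + 1]] <- c(by, bx, a_ax)

    # rasterize the rotated ellipse inside its bounding box
    r0 <- max(1L, floor(by - a_ax - 1)); r1 <- min(n, ceiling(by + a_ax + 1))
    c0 <- max(1L, floor(bx - a_ax - 1)); c1 <- min(n, ceiling(bx + a_ax + 1))
    ys <- r0:r1; xs <- c0:c1
    dy <- matrix(ys - by, length(ys), length(xs))
    dx <- matrix(xs - bx, length(ys), length(xs), byrow = TRUE)
    u <- dy * cos(theta) + dx * sin(theta)
    v <- -dy * sin(theta) + dx * cos(theta)
    inside <- (u / a_ax)^2 + (v / b_ax)^2 <= 1
    npx <- sum(inside)
    for (ch in 1:3) {
      plane <- px[ys, xs, ch]
      plane[inside] <- spec$chromogen_color[ch]
      px[ys, xs, ch] <- plane
    }
    truth[[i]] <- tibble(
      blob_id = i, kind = kinds[i], center_y = by, center_x = bx,
      requested_area_um2 = all_areas[i], pixel_count = npx,
      area_um2 = npx * ps^2
    )
  }

  truth <- dplyr::bind_rows(truth)
  if (nrow(truth) > 0) {
    ref_params <- segmentation_params(base_threshold = spec$base_threshold,
                                      transform_mode = spec$transform_mode)
    truth$expected_cluster <- classify_area(truth$area_um2, ref_params)
  } else {
    truth <- tibble(blob_id = integer(), kind = character(),
                    center_y = numeric(), center_x = numeric(),
                    requested_area_um2 = numeric(), pixel_count = integer(),
                    area_um2 = numeric(), expected_cluster = integer())
  }

  if (spec$noise_sd > 0) {
    noise <- array(rnorm(length(px), 0, spec$noise_sd), dim(px))
    px <- pmin(pmax(round(px + noise), 0), 255)
  }

  list(image = rgb_image(px, pixel_size_um = ps),
       truth = truth,
       tissue_px = sum(tissue))
}
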