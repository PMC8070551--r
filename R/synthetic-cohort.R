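#' Specification of a synthetic multi-donor cohort
#'
#' Defines donor groups with mean chromogen-blob densities (per mm^2 of
#' tissue) for cluster-1 (single macrophages / small groups) and cluster-2
#' (larger groups) regions, plus a between-donor coefficient of variation.
#' Each donor's densities are the group means times a log-normal
#' multiplier with that CV; per-tile blob counts are Poisson with the
#' donor's density times the tile's tissue area; blob areas are log-normal
#' truncated to the target cluster's range.
#'
#' @param groups data frame (or tibble) with columns `group`, `n_donors`,
#'   `c1_density_per_mm2`, `c2_density_per_mm2`, `cv`.
#' @param tiles_per_donor number of tiles per donor (default 4).
#' @param tile a [tile_spec] template; its colors, size, noise, and
#'   cluster-1 area distribution are reused (default
#'   `tile_spec(n_smears = 0)`).
#' @param c2_area_meanlog,c2_area_sdlog,c2_area_range log-normal parameters
#'   and truncation range of cluster-2 blob areas in um^2.
#' @param marker marker label written into the manifest.
#' @param seed root RNG seed; per-donor and per-tile seeds are derived
#'   deterministically from it.
#' @return A `cohort_spec` list.
#' @examples
#' groups <- data.frame(group = c("control", "tumor"), n_donors = 5,
#'                      c1_density_per_mm2 = c(200, 600),
#'                      c2_density_per_mm2 = c(10, 30), cv = 0.3)
#' cohort_spec(groups, seed = 7)
#' @export
cohort_spec <- function(groups,
                        tiles_per_donor = 4,
                        tile = tile_spec(),
                        c2_area_meanlog = log(700),
                        c2_area_sdlog = 0.4,
                        c2_area_range = c(320, 1900),
                        marker = "synthetic",
                        seed = 1L) {
  groups <- as_tibble(groups)
  needed <- c("group", "n_donors", "c1_density_per_mm2",
              "c2_density_per_mm2", "cv")
  if (!all(needed %in% names(groups))) {
    abort(paste("`groups` needs columns:", paste(needed, collapse = ", ")))
  }
  if (any(groups$n_donors < 2)) abort("each group needs >= 2 donors.")
  if (any(groups$c1_density_per_mm2 < 0 | groups$c2_density_per_mm2 < 0)) {
    abort("densities must be >= 0.")
  }
  stopifnot(inherits(tile, "tile_spec"))
  structure(
    list(groups = groups, tiles_per_donor = as.integer(tiles_per_donor),
         tile = tile, c2_area_meanlog = c2_area_meanlog,
         c2_area_sdlog = c2_area_sdlog, c2_area_range = c2_area_range,
         marker = marker, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# nominal tissue area of one template tile, in um^2 / mm^2
tile_tissue_um2 <- function(tile) {
  tile$tissue_fraction * (tile$tile_size_px * tile$pixel_size_um)^2
}

rlnorm_trunc <- function(n, meanlog, sdlog, range) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      a <- rlnorm(1, meanlog, sdlog)
      if (a >= range[1] && a <= range[2]) { out[i] <- a; break }
    }
    if (out[i] == 0) {
      abort("truncated log-normal draw failed; widen the area range.",
            class = "dabquant_generation_error")
    }
  }
  out
}

# One stochastic realization of a cohort: donor densities, per-tile blob
# counts and areas. Shared by generate_cohort() (which rasterizes it) and
# simulate_cohort_fractions() (which integrates areas analytically).
draw_cohort <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    tissue_mm2 <- tile_tissue_um2(spec$tile) / 1e6
    sl <- function(cv) sqrt(log(1 + cv^2))
    donors <- list(); blobs <- list(); idx <- 0L
    for (gi in seq_len(nrow(spec$groups))) {
      g <- spec$groups[gi, ]
      for (di in seq_len(g$n_donors)) {
        idx <- idx + 1L
        donor_id <- sprintf("D%02d", idx)
        s <- sl(g$cv)
        mult1 <- rlnorm(1, -s^2 / 2, s) # mean-1 multipliers
        mult2 <- rlnorm(1, -s^2 / 2, s)
        d1 <- g$c1_density_per_mm2 * mult1
        d2 <- g$c2_density_per_mm2 * mult2
        donors[[idx]] <- tibble(
          donor_id = donor_id, group = g$group,
          c1_density = d1, c2_density = d2,
          tissue_area_um2 = spec$tiles_per_donor * tissue_mm2 * 1e6
        )
        for (ti in seq_len(spec$tiles_per_donor)) {
          n1 <- rpois(1, d1 * tissue_mm2)
          n2 <- rpois(1, d2 * tissue_mm2)
          a1 <- if (n1 > 0) {
            rlnorm_trunc(n1, spec$tile$blob_area_meanlog,
                         spec$tile$blob_area_sdlog,
                         spec$tile$blob_area_range)
          } else numeric(0)
          a2 <- if (n2 > 0) {
            rlnorm_trunc(n2, spec$c2_area_meanlog, spec$c2_area_sdlog,
                         spec$c2_area_range)
          } else numeric(0)
          if (n1 + n2 > 0) {
            blobs[[length(blobs) + 1]] <- tibble(
              donor_id = donor_id, tile_index = ti,
              cluster = c(rep(1L, n1), rep(2L, n2)),
              area_um2 = c(a1, a2)
            )
          }
        }
      }
    }
    list(donors = dplyr::bind_rows(donors),
         blobs = dplyr::bind_rows(
           blobs,
           tibble(donor_id = character(), tile_index = integer(),
                  cluster = integer(), area_um2 = numeric())))
  })
}

# ground-truth normalized fractions of one cohort draw
cohort_fractions <- function(draw) {
  tidyr::expand_grid(donor_id = draw$donors$donor_id,
                     cluster = c(1L, 2L)) |>
    dplyr::left_join(
      draw$blobs |>
        dplyr::group_by(.data$donor_id, .data$cluster) |>
        dplyr::summarise(total = sum(.data$area_um2), .groups = "drop"),
      by = c("donor_id", "cluster")) |>
    dplyr::left_join(draw$donors[, c("donor_id", "group",
                                     "tissue_area_um2")],
                     by = "donor_id") |>
    dplyr::mutate(fraction_base =
                    dplyr::coalesce(.data$total, 0) / .data$tissue_area_um2) |>
    dplyr::select("donor_id", "group", "cluster", "fraction_base")
}

#' Ground-truth donor fractions from the cohort model, without rasterizing
#'
#' Draws cohorts from exactly the sampling model behind
#' [generate_cohort()] — log-normal donor multipliers, Poisson tile
#' counts, truncated log-normal blob areas — and returns the resulting
#' normalized area fractions per donor and cluster, skipping image
#' rendering and segmentation. This is the fast path for large-replicate
#' statistical studies (type-I error calibration, power) where the
#' quantity under test is the group comparison, not the segmentation; a
#' test verifies the rendered pipeline recovers these fractions.
#'
#' @param spec a [cohort_spec].
#' @param n_replicates number of independent cohort draws.
#' @return Tibble: `replicate`, `donor_id`, `group`, `cluster`,
#'   `fraction_base`.
#' @export
simulate_cohort_fractions <- function(spec, n_replicates = 1) {
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    draw <- draw_cohort(spec, seed = derive_seed(spec$seed, r))
    dplyr::bind_cols(tibble(replicate = rep(r, 2 * nrow(draw$donors))),
                     cohort_fractions(draw))
  })
}

#' Generate a synthetic cohort on disk
#'
#' Rasterizes one cohort draw: writes per-donor tile TIFFs, per-tile
#' ground-truth JSON, and a donor manifest CSV (`donor_id, marker, group,
#' tissue_area_um2, tiles_glob`) compatible with [run_full()]. The
#' manifest's tissue areas are measured from the rendered tiles with
#' [estimate_tissue_mask()]. Deterministic for a fixed spec.
#'
#' @param spec a [cohort_spec].
#' @param output_dir writable output directory (created if missing).
#' @return Path to the manifest CSV, invisibly.
#' @export
generate_cohort <- function(spec, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(output_dir, 2) != 0) {
    abort(sprintf("directory not writable: %s", output_dir),
          class = "dabquant_io_error")
  }
  draw <- draw_cohort(spec)
  manifest <- list()
  for (i in seq_len(nrow(draw$donors))) {
    donor <- draw$donors$donor_id[i]
    ddir <- file.path(output_dir, donor)
    dir.create(ddir, showWarnings = FALSE)
    tissue_um2 <- 0
    for (ti in seq_len(spec$tiles_per_donor)) {
      areas <- draw$blobs$area_um2[draw$blobs$donor_id == donor &
                                     draw$blobs$tile_index == ti]
      tspec <- spec$tile
      tspec$blob_areas_um2 <- areas
      tspec$n_smears <- 0L
      tspec$seed <- derive_seed(spec$seed, i * 1000 + ti)
      gen <- generate_tile(tspec)
      stem <- file.path(ddir, sprintf("%s_r0_c%d", donor, ti - 1L))
      write_rgb_image(gen$image, paste0(stem, ".tif"))
      jsonlite::write_json(
        list(truth = gen$truth, tissue_px = gen$tissue_px,
             pixel_size_um = tspec$pixel_size_um),
        paste0(stem, "_truth.json"), dataframe = "columns", digits = NA)
      tissue_um2 <- tissue_um2 +
        estimate_tissue_mask(gen$image)$tissue_area_um2
    }
    manifest[[i]] <- tibble(
      donor_id = donor, marker = spec$marker,
      group = draw$donors$group[i],
      tissue_area_um2 = tissue_um2,
      tiles_glob = file.path(donor, "*.tif")
    )
  }
  mpath <- file.path(output_dir, "manifest.csv")
  write.csv(dplyr::bind_rows(manifest), mpath, row.names = FALSE)
  invisible(mpath)
}
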