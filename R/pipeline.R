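#' Fully resolved pipeline configuration
#'
#' Materializes every tunable of a run — marker preset or explicit
#' threshold, window, smoothing, transform, connectivity, tile size, pixel
#' size, tissue-mask rule, contrast stretch, significance level, seed —
#' into one explicit list. The resolved configuration is written as YAML
#' next to the outputs of [run_segment()] / [run_full()], so a run is
#' reproducible from its own record.
#'
#' @param marker marker preset passed to [segmentation_params()].
#' @param base_threshold explicit base threshold overriding the preset.
#' @param transform_mode,window_below,window_above,sigma_px,connectivity
#'   segmentation overrides, see [segmentation_params()].
#' @param pixel_size_um physical pixel size of the input scans.
#' @param tile_size_px tile edge length for whole-slide inputs.
#' @param background_min_intensity tissue-mask background cutoff.
#' @param stretch apply the percentile contrast stretch before
#'   segmentation.
#' @param alpha significance level for group comparisons.
#' @param seed RNG seed recorded with the run.
#' @return A `run_config` list with a `params` element holding the
#'   [segmentation_params].
#' @export
run_config <- function(marker = "CD68", base_threshold = NULL,
                       transform_mode = "inv_red_plus_green",
                       window_below = 3, window_above = 4, sigma_px = 5,
                       connectivity = 8,
                       pixel_size_um = 0.221, tile_size_px = 1000,
                       background_min_intensity = 240,
                       stretch = FALSE, alpha = 0.05, seed = 1L) {
  params <- segmentation_params(
    marker = marker, base_threshold = base_threshold,
    window_below = window_below, window_above = window_above,
    sigma_px = sigma_px, connectivity = connectivity,
    transform_mode = transform_mode)
  structure(
    list(params = params, pixel_size_um = pixel_size_um,
         tile_size_px = as.integer(tile_size_px),
         background_min_intensity = background_min_intensity,
         stretch = stretch, alpha = alpha, seed = as.integer(seed)),
    class = "run_config"
  )
}

write_resolved_config <- function(config, path) {
  flat <- c(config$params[setdiff(names(config$params), "marker")],
            list(marker = config$params$marker),
            config[setdiff(names(config), "params")])
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Segment whole slides into per-tile CSVs and overlays
#'
#' For each input image: read, optionally contrast-stretch, tile, segment
#' every tile at the three window thresholds, and write one region CSV and
#' one overlay PNG per tile plus a per-slide summary CSV. The resolved
#' configuration is written once to `out_dir/config.yaml`.
#'
#' @param config a [run_config].
#' @param slide_paths character vector of TIFF/PNG paths.
#' @param out_dir output directory.
#' @return Tibble with one row per tile (`slide_id`, `tile_id`, `csv`,
#'   `overlay`, region counts), invisibly. An empty `slide_paths` is a
#'   warning and a no-op.
#' @export
run_segment <- function(config, slide_paths, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (length(slide_paths) == 0) {
    warn("no input slides; nothing to do.")
    return(invisible(tibble()))
  }
  missing <- slide_paths[!file.exists(slide_paths)]
  if (length(missing) > 0) {
    abort(sprintf("input not readable: %s", paste(missing, collapse = ", ")),
          class = "dabquant_io_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_resolved_config(config, file.path(out_dir, "config.yaml"))
  rows <- list()
  for (sp in slide_paths) {
    slide_id <- tools::file_path_sans_ext(basename(sp))
    img <- read_rgb_image(sp, pixel_size_um = config$pixel_size_um)
    if (config$stretch) img <- stretch_contrast(img)
    tiles <- split_into_tiles(img, config$tile_size_px)
    sdir <- file.path(out_dir, slide_id)
    dir.create(sdir, showWarnings = FALSE)
    for (i in seq_len(nrow(tiles))) {
      tid <- sprintf("%s_%s", slide_id, tiles$tile_id[i])
      res <- segment_tile(tiles$tile[[i]], config$params, tile_id = tid)
      csv <- file.path(sdir, paste0(tid, ".csv"))
      ovl <- file.path(sdir, paste0(tid, "_overlay.png"))
      write_tile_csv(res, csv)
      write_rgb_image(render_overlay(tiles$tile[[i]], res), ovl)
      rows[[length(rows) + 1]] <- tibble(
        slide_id = slide_id, tile_id = tid, csv = csv, overlay = ovl,
        n_regions_base = sum(res$threshold ==
                               attr(res, "thresholds")[["t_base"]]))
    }
    slide_rows <- dplyr::bind_rows(rows)
    write.csv(slide_rows[slide_rows$slide_id == slide_id, ],
              file.path(sdir, "summary.csv"), row.names = FALSE)
  }
  invisible(dplyr::bind_rows(rows))
}

#' Run the full pipeline from a donor manifest
#'
#' Reads a donor manifest (`donor_id, marker, group, tissue_area_um2,
#' tiles_glob`; globs resolved relative to the manifest), segments every
#' tile of every donor, summarizes donors, compares groups, and writes
#' `donor_summary.csv`, `group_anova.csv`, `group_pairwise.csv`, a bar
#' figure per cluster, and the resolved configuration.
#'
#' A manifest `tissue_area_um2` of `NA` is filled in by summing
#' [estimate_tissue_mask()] over the donor's tiles.
#'
#' @param config a [run_config].
#' @param manifest_path path to the manifest CSV.
#' @param out_dir output directory.
#' @return List with `summaries` (donor_summary tibble) and `comparison`
#'   (`group_comparison`), invisibly.
#' @export
run_full <- function(config, manifest_path, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path),
          class = "dabquant_io_error")
  }
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  needed <- c("donor_id", "marker", "group", "tissue_area_um2", "tiles_glob")
  if (!all(needed %in% names(man))) {
    abort(sprintf("manifest must have columns: %s",
                  paste(needed, collapse = ", ")),
          class = "dabquant_parse_error")
  }
  base <- dirname(manifest_path)
  tile_sets <- lapply(seq_len(nrow(man)), function(i) {
    Sys.glob(file.path(base, man$tiles_glob[i]))
  })
  empty <- man$donor_id[lengths(tile_sets) == 0]
  if (length(empty) > 0) {
    abort(sprintf("no tiles found for donor(s): %s",
                  paste(empty, collapse = ", ")),
          class = "dabquant_validation_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_resolved_config(config, file.path(out_dir, "config.yaml"))

  summaries <- purrr::map_dfr(seq_len(nrow(man)), function(i) {
    tiles <- lapply(tile_sets[[i]], read_rgb_image,
                    pixel_size_um = config$pixel_size_um)
    if (config$stretch) tiles <- lapply(tiles, stretch_contrast)
    results <- purrr::imap(tiles, function(t, j) {
      segment_tile(t, config$params,
                   tile_id = tools::file_path_sans_ext(
                     basename(tile_sets[[i]][j])))
    })
    tissue <- man$tissue_area_um2[i]
    if (is.na(tissue)) {
      tissue <- sum(vapply(tiles, function(t) {
        estimate_tissue_mask(t, config$background_min_intensity)$tissue_area_um2
      }, numeric(1)))
    }
    summarize_donor(results, tissue, config$params,
                    donor_id = man$donor_id[i], marker = man$marker[i])
  })
  summaries <- structure(summaries,
                         class = c("donor_summary", class(summaries)))
  grouping <- setNames(man$group, man$donor_id)
  comparison <- compare_groups(summaries, grouping, alpha = config$alpha)

  write.csv(as.data.frame(summaries),
            file.path(out_dir, "donor_summary.csv"), row.names = FALSE)
  write.csv(as.data.frame(comparison$anova),
            file.path(out_dir, "group_anova.csv"), row.names = FALSE)
  write.csv(as.data.frame(comparison$pairwise),
            file.path(out_dir, "group_pairwise.csv"), row.names = FALSE)
  p <- autoplot(summaries)
  ggplot2::ggsave(file.path(out_dir, "donor_fractions.png"), p,
                  width = 8, height = 4, dpi = 150)
  invisible(list(summaries = summaries, comparison = comparison))
}
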