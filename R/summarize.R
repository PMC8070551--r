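#' Donor-level normalized area fractions with threshold-window error bars
#'
#' Sums segmented region area per cluster and per window threshold across
#' all tiles of one donor/marker, then divides by the donor's tissue
#' section area. The base-threshold fraction is the reported value; the
#' minimum and maximum across the three thresholds give `error_low` and
#' `error_high` — the error of the detection method, not biological
#' variance. Cluster 3 (unspecific staining) areas are summed but excluded
#' from the reported fractions; rows are emitted for clusters 1 and 2 only.
#'
#' @param results list of `tile_result`s (or one row-bound `tile_result`)
#'   for the donor.
#' @param tissue_area_um2 whole tissue-section area of the donor in um^2
#'   (> 0), from [estimate_tissue_mask()] summed over tiles.
#' @param params the [segmentation_params] used for segmentation (supplies
#'   the threshold window).
#' @param donor_id,marker labels carried into the output.
#' @return A `donor_summary` tibble with one row per cluster in {1, 2}:
#'   `donor_id`, `marker`, `cluster`, `tissue_area_um2`,
#'   `area_tmin/area_base/area_tmax` (um^2), `fraction_tmin/fraction_base/
#'   fraction_tmax`, `error_low`, `error_high`.
#' @export
summarize_donor <- function(results, tissue_area_um2, params,
                            donor_id = "donor", marker = NA_character_) {
  if (!is.numeric(tissue_area_um2) || tissue_area_um2 <= 0) {
    abort("`tissue_area_um2` must be a positive number.")
  }
  if (inherits(results, "tile_result")) results <- list(results)
  thr <- attr(results[[1]], "thresholds") %||% window_thresholds(params)
  all_rows <- dplyr::bind_rows(lapply(results, as_tibble))
  if (!"cluster" %in% names(all_rows)) { # schema-less empty input
    all_rows <- tibble(cluster = integer(), threshold = integer(),
                       area_um2 = numeric())
  }
  grid <- tidyr::expand_grid(cluster = c(1L, 2L),
                             threshold = as.integer(unname(thr)))
  sums <- all_rows |>
    dplyr::filter(.data$cluster %in% c(1L, 2L)) |>
    dplyr::group_by(.data$cluster, .data$threshold) |>
    dplyr::summarise(total_area_um2 = sum(.data$area_um2), .groups = "drop")
  sums <- grid |>
    dplyr::left_join(sums, by = c("cluster", "threshold")) |>
    dplyr::mutate(total_area_um2 = dplyr::coalesce(.data$total_area_um2, 0))
  wide <- lapply(split(sums, sums$cluster), function(d) {
    a <- setNames(d$total_area_um2, names(thr)[match(d$threshold, thr)])
    f <- a / tissue_area_um2
    tibble(
      cluster = d$cluster[1],
      area_tmin = a[["t_min"]], area_base = a[["t_base"]],
      area_tmax = a[["t_max"]],
      fraction_tmin = f[["t_min"]], fraction_base = f[["t_base"]],
      fraction_tmax = f[["t_max"]],
      error_low = min(f), error_high = max(f)
    )
  })
  out <- dplyr::bind_cols(
    tibble(donor_id = rep(donor_id, 2), marker = rep(marker, 2)),
    dplyr::bind_rows(wide),
    tibble(tissue_area_um2 = rep(tissue_area_um2, 2))
  )
  structure(out, class = c("donor_summary", class(out)))
}

#' @export
print.donor_summary <- function(x, ...) {
  cat("<donor_summary> normalized segmented-area fractions\n")
  NextMethod()
}
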