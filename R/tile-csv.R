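#' Write / read the per-tile region CSV
#'
#' One CSV per tile holds the feature regions of all three window
#' thresholds: columns `tile_id, threshold, region_id, pixel_count,
#' area_um2, cluster`, comma-separated, header row, UTF-8, areas printed
#' with 4 decimals. `read_tile_csv(write_tile_csv(x))` reproduces the
#' region table exactly at that precision.
#'
#' @param result a `tile_result` from [segment_tile()].
#' @param path destination CSV path.
#' @return `write_tile_csv`: `path`, invisibly. `read_tile_csv`: a
#'   `tile_result` (attributes `thresholds` and `pixel_size_um` are
#'   restored from the file contents and from the `pixel_size_um`
#'   argument).
#' @export
write_tile_csv <- function(result, path) {
  stopifnot(inherits(result, "tile_result"))
  cols <- c("tile_id", "threshold", "region_id", "pixel_count",
            "area_um2", "cluster")
  df <- as.data.frame(result)
  if (nrow(df) == 0) {
    df <- data.frame(tile_id = character(), threshold = integer(),
                     region_id = integer(), pixel_count = integer(),
                     area_um2 = numeric(), cluster = integer())
  }
  df <- df[, cols]
  df$area_um2 <- sprintf("%.4f", df$area_um2)
  thr <- attr(result, "thresholds")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# thresholds: %d,%d,%d; pixel_size_um: %.6g",
                     thr[1], thr[2], thr[3], attr(result, "pixel_size_um")),
             con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tile_csv
#' @param pixel_size_um fallback pixel size if the file header lacks one.
#' @export
read_tile_csv <- function(path, pixel_size_um = 0.221) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "dabquant_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  thr <- NULL
  if (length(lines) > 0 && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1],
                    regexec("thresholds: (\\d+),(\\d+),(\\d+)", lines[1]))[[1]]
    if (length(m) == 4) {
      thr <- setNames(as.integer(m[2:4]), c("t_min", "t_base", "t_max"))
    }
    ps <- regmatches(lines[1],
                     regexec("pixel_size_um: ([0-9.eE+-]+)", lines[1]))[[1]]
    if (length(ps) == 2) pixel_size_um <- as.numeric(ps[2])
    lines <- lines[-1]
  }
  wanted <- c("tile_id", "threshold", "region_id", "pixel_count",
              "area_um2", "cluster")
  header <- strsplit(lines[1], ",")[[1]]
  missing_cols <- setdiff(wanted, header)
  if (length(missing_cols) > 0) {
    abort(sprintf("line 1: missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "dabquant_parse_error")
  }
  df <- tryCatch(
    read.csv(text = lines, colClasses = c(
      tile_id = "character", threshold = "integer", region_id = "integer",
      pixel_count = "integer", area_um2 = "numeric", cluster = "integer")),
    warning = function(w) abort(paste("malformed CSV:", conditionMessage(w)),
                                class = "dabquant_parse_error"),
    error = function(e) abort(paste("malformed CSV:", conditionMessage(e)),
                              class = "dabquant_parse_error")
  )
  bad <- which(is.na(df$threshold) | is.na(df$area_um2) | is.na(df$cluster))
  if (length(bad) > 0) {
    abort(sprintf("line %d: non-numeric or missing cell.", bad[1] + 1L),
          class = "dabquant_parse_error")
  }
  if (is.null(thr)) {
    tv <- sort(unique(df$threshold))
    thr <- setNames(as.integer(c(tv[1], tv[pmin(2, length(tv))],
                                 tv[length(tv)])),
                    c("t_min", "t_base", "t_max"))
  }
  new_tile_result(as_tibble(df[, wanted]), thresholds = thr, params = NULL,
                  pixel_size_um = pixel_size_um)
}
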