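make_px <- function(r, g, b) rgb_image(array(as.integer(c(r, g, b)), c(1, 1, 3)))

test_that("chromogen signal transforms follow their formulas with saturation", {
  cases <- list(
    # r, g, b, mode, expected
    list(255, 0, 0, "inv_red_plus_green", 0),
    list(0, 255, 0, "inv_red_plus_green", 255), # 510 saturated
    list(140, 110, 0, "inv_red_plus_green", 225),
    list(255, 255, 0, "dual_inverted", 0),
    list(0, 0, 0, "dual_inverted", 255),   # 510 saturated
    list(100, 200, 0, "dual_inverted", 210),
    list(0, 0, 70, "blue_deficit", 185),
    list(0, 0, 255, "blue_deficit", 0)
  )
  for (cs in cases) {
    sig <- compute_signal(make_px(cs[[1]], cs[[2]], cs[[3]]), cs[[4]])
    expect_equal(as.integer(sig), cs[[5]], info = cs[[4]])
    expect_equal(attr(sig, "stage"), "raw_signal")
  }
  # unsaturated diagnostic mode keeps the wide sum
  wide <- compute_signal(make_px(0, 255, 0), "inv_red_plus_green", saturate = FALSE)
  expect_equal(as.integer(wide), 510)
  expect_error(compute_signal(make_px(0, 0, 0), "nope"))
})

test_that("gaussian smoothing matches a direct-convolution oracle", {
  # constant image is a fixed point for any sigma
  const <- signal_image_for_test(matrix(123L, 30, 30))
  expect_true(all(unclass(gaussian_smooth(const, 5)) == 123L))

  # sigma 0 returns the input values unchanged
  set.seed(21)
  v <- matrix(sample(0:255, 400, TRUE), 20)
  s0 <- gaussian_smooth(signal_image_for_test(v), 0)
  expect_identical(unclass(s0)[, ], v)
  expect_equal(attr(s0, "stage"), "smoothed")

  # single impulse: center equals the discrete central weight x 255
  imp <- matrix(0, 101, 101); imp[51, 51] <- 255
  sm <- gaussian_smooth(signal_image_for_test(imp), 5)
  i <- -20:20
  k1 <- exp(-0.5 * i^2 / 25); k1 <- k1 / sum(k1)
  expect_equal(unclass(sm)[51, 51], floor(255 * k1[21]^2 + 0.5))

  # full-field agreement with the naive 2-D oracle, including borders
  small <- matrix(sample(0:255, 15 * 13, TRUE), 15, 13)
  got <- gaussian_smooth(signal_image_for_test(small), 2.5)
  want <- floor(gaussian_oracle(small, 2.5) + 0.5)
  expect_identical(unclass(got)[, ], matrix(as.integer(want), 15, 13))

  # smoothing an already-smoothed stage is refused
  expect_error(gaussian_smooth(sm, 5), "already")
})

test_that("binarization is inclusive at the threshold", {
  v <- matrix(c(9L, 10L, 11L, 200L), 2)
  m <- binarize(smoothed_for_test(v), 10)
  expect_identical(as.integer(m), c(0L, 1L, 1L, 1L)) # value == T is foreground

  expect_equal(sum(binarize(smoothed_for_test(matrix(5L, 4, 4)), 10)), 0)

  set.seed(22)
  r <- matrix(sample(0:255, 2500, TRUE), 50)
  expect_equal(sum(binarize(smoothed_for_test(r), 77)), sum(r >= 77))
})

test_that("region measurement applies the strict area filter and cluster map", {
  p <- segmentation_params(marker = "CD68")
  mk_label <- function(counts) {
    # one region per non-adjacent row of a wide matrix
    m <- matrix(0L, 2 * length(counts), max(counts))
    for (i in seq_along(counts)) m[2 * i - 1, seq_len(counts[i])] <- 1L
    label_connected(m, 4)
  }
  lab <- mk_label(c(100, 1000, 50000))
  out <- measure_filter_cluster(lab, 0.221, p, 13)
  # 100 px = 4.8841 um2 -> discarded; 1000 px = 48.841 -> cluster 1;
  # 50000 px = 2442.05 -> cluster 3
  expect_equal(nrow(out), 2)
  expect_equal(out$area_um2, c(1000, 50000) * 0.221^2)
  expect_equal(out$cluster, c(1L, 3L))
  expect_equal(out$threshold, c(13L, 13L))

  # boundary areas via a pixel size making counts hit bounds exactly
  lab2 <- mk_label(c(10, 300, 301, 2000, 2001))
  out2 <- measure_filter_cluster(lab2, 1, segmentation_params(
    base_threshold = 13), 13)
  expect_equal(out2$pixel_count, c(300, 301, 2000, 2001)) # 10 discarded
  expect_equal(out2$cluster, c(1L, 2L, 2L, 3L))
})

test_that("cluster map partitions (10, Inf) with half-open boundaries", {
  p <- segmentation_params(marker = "CD68")
  sweep <- c(9.99, 10.0, 10.01, 300.0, 300.01, 2000.0, 2000.01)
  expect_identical(classify_area(sweep, p),
                   c(NA_integer_, NA_integer_, 1L, 1L, 2L, 2L, 3L))
  # every retained area maps to exactly one cluster
  set.seed(23)
  areas <- exp(runif(500, log(10.001), log(10000)))
  cl <- classify_area(areas, p)
  expect_false(anyNA(cl))
  expect_true(all(cl %in% 1:3))
})

test_that("marker presets carry the established thresholds and window", {
  for (cfg in list(c("CD68", 13), c("CD80", 18), c("CD163", 21))) {
    p <- segmentation_params(marker = cfg[1])
    expect_equal(p$base_threshold, as.integer(cfg[2]))
    expect_equal(unname(window_thresholds(p)),
                 as.integer(cfg[2]) + c(-3L, 0L, 4L))
    expect_equal(p$sigma_px, 5)
    expect_equal(p$min_area_um2, 10)
    expect_equal(p$cluster1_max_um2, 300)
    expect_equal(p$cluster2_max_um2, 2000)
  }
  expect_error(segmentation_params(marker = "CD4"), "marker")
  expect_error(segmentation_params(base_threshold = 2, window_below = 3),
               "window")
})

test_that("segment_tile is deterministic, monotone in threshold, and empty on blank tiles", {
  p <- default_synth_params()
  blank <- rgb_image(array(rep(c(250L, 250L, 252L), each = 1e4),
                           c(100, 100, 3)))
  res <- segment_tile(blank, p)
  expect_equal(nrow(res), 0)
  expect_equal(unname(attr(res, "thresholds")), c(97L, 100L, 104L))

  spec <- tile_spec(tile_size_px = 300, n_blobs = 4, seed = 31)
  tile <- generate_tile(spec)$image
  r1 <- segment_tile(tile, p, "t")
  r2 <- segment_tile(tile, p, "t")
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # pre-filter foreground is non-increasing in the threshold
  sm <- gaussian_smooth(compute_signal(tile, p$transform_mode), p$sigma_px)
  counts <- vapply(window_thresholds(p),
                   function(t) sum(binarize(sm, t)), numeric(1))
  expect_true(counts[["t_max"]] <= counts[["t_base"]])
  expect_true(counts[["t_base"]] <= counts[["t_min"]])
})

test_that("overlay recolors exactly the region pixels by cluster", {
  spec <- tile_spec(tile_size_px = 900, n_blobs = 3, n_smears = 1,
                    blob_area_range = c(100, 295),
                    blob_area_meanlog = log(200),
                    smear_area_range = c(2100, 2400), seed = 32)
  gen <- generate_tile(spec)
  p <- default_synth_params()
  res <- segment_tile(gen$image, p)
  base_t <- attr(res, "thresholds")[["t_base"]]
  ov <- render_overlay(gen$image, res, base_t)
  rows <- res[res$threshold == base_t, ]
  # per-color pixel counts match the region pixel counts per cluster
  pure <- function(col) {
    sum(unclass(ov)[, , 1] == col[1] & unclass(ov)[, , 2] == col[2] &
          unclass(ov)[, , 3] == col[3])
  }
  expect_equal(pure(c(0, 255, 0)), sum(rows$pixel_count[rows$cluster == 1]))
  expect_equal(pure(c(0, 0, 255)), sum(rows$pixel_count[rows$cluster == 3]))
  expect_gt(sum(rows$cluster == 3), 0) # the smear is present and blue

  # empty result leaves the tile untouched
  blank <- rgb_image(array(250L, c(50, 50, 3)))
  res0 <- segment_tile(blank, p)
  expect_identical(unclass(render_overlay(blank, res0))[, , ],
                   unclass(blank)[, , ])
  expect_error(render_overlay(gen$image, res, 250), "threshold")
})
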