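make_result <- function(areas_um2, clusters, thresholds = c(97L, 100L, 104L),
                        pixel_size_um = 0.221) {
  # same regions at every threshold unless a list is given per threshold
  if (!is.list(areas_um2)) {
    areas_um2 <- list(areas_um2, areas_um2, areas_um2)
    clusters <- list(clusters, clusters, clusters)
  }
  rows <- purrr::map2_dfr(seq_along(thresholds), thresholds, function(i, t) {
    a <- areas_um2[[i]]
    if (length(a) == 0) return(tibble::tibble())
    tibble::tibble(
      tile_id = "t", threshold = t, region_id = seq_along(a),
      pixel_count = as.integer(round(a / pixel_size_um^2)),
      area_um2 = a, cluster = clusters[[i]]
    )
  })
  structure(rows,
            thresholds = stats::setNames(thresholds,
                                         c("t_min", "t_base", "t_max")),
            params = NULL, pixel_size_um = pixel_size_um,
            class = c("tile_result", class(rows)))
}

test_that("per-tile CSV round-trips exactly at the printed precision", {
  res <- make_result(c(48.841, 500.25, 2500.0), c(1L, 2L, 3L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_tile_csv(res, f)
  back <- read_tile_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(res), tolerance = 1e-12)
  expect_equal(attr(back, "thresholds"), attr(res, "thresholds"))

  # empty result: header only, reads back empty
  res0 <- make_result(numeric(0), integer(0))
  f0 <- withr::local_tempfile(fileext = ".csv")
  write_tile_csv(res0, f0)
  expect_equal(nrow(read_tile_csv(f0)), 0)

  # area precision: 4 decimals survive the trip
  res4 <- make_result(1234.5678, 2L)
  f4 <- withr::local_tempfile(fileext = ".csv")
  write_tile_csv(res4, f4)
  expect_equal(read_tile_csv(f4)$area_um2, rep(1234.5678, 3))
})

test_that("malformed tile CSVs fail with the offending column or line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tile_id,threshold,region_id,pixel_count,area_um2",
               "t,13,1,100,4.0"), f) # cluster column missing
  expect_error(read_tile_csv(f), "cluster", class = "dabquant_parse_error")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tile_id,threshold,region_id,pixel_count,area_um2,cluster",
               "t,13,1,100,oops,1"), f2)
  expect_error(read_tile_csv(f2), class = "dabquant_parse_error")
})

test_that("donor summary normalizes per cluster with window error bars", {
  p <- default_synth_params()
  res <- make_result(48.841, 1L)
  s <- summarize_donor(res, 1e5, p, donor_id = "D01", marker = "CD68")
  expect_equal(nrow(s), 2) # clusters 1 and 2 always reported
  c1 <- s[s$cluster == 1, ]
  expect_equal(c1$fraction_base, 4.8841e-4)
  expect_equal(c1$error_low, 4.8841e-4)  # same regions at all thresholds
  expect_equal(c1$error_high, 4.8841e-4)
  expect_equal(s$fraction_base[s$cluster == 2], 0)

  # no regions at all -> all fractions and error bars zero
  s0 <- summarize_donor(make_result(numeric(0), integer(0)), 1e5, p)
  expect_true(all(s0$fraction_base == 0) && all(s0$error_high == 0))

  # cluster 3 regions are excluded from reported fractions
  s3 <- summarize_donor(make_result(c(5000, 3000), c(3L, 3L)), 1e5, p)
  expect_true(all(s3$fraction_base == 0))

  expect_error(summarize_donor(res, 0, p), "positive")
})

test_that("window containment and normalization linearity hold", {
  p <- default_synth_params()
  # distinct areas per threshold: more area at lower thresholds
  res <- make_result(list(c(120, 350), c(100, 320), c(80, 310)),
                     list(c(1L, 2L), c(1L, 2L), c(1L, 2L)))
  s <- summarize_donor(res, 2e5, p)
  expect_true(all(s$error_low <= s$fraction_base + 1e-15))
  expect_true(all(s$fraction_base <= s$error_high + 1e-15))
  expect_equal(s$fraction_base[s$cluster == 1], 100 / 2e5)
  expect_equal(s$error_low[s$cluster == 1], 80 / 2e5)
  expect_equal(s$error_high[s$cluster == 1], 120 / 2e5)

  # doubling every region area doubles every fraction exactly
  res2 <- make_result(list(c(240, 700), c(200, 640), c(160, 620)),
                      list(c(1L, 2L), c(1L, 2L), c(1L, 2L)))
  s2 <- summarize_donor(res2, 2e5, p)
  expect_equal(s2$fraction_base, 2 * s$fraction_base)
  expect_equal(s2$error_high, 2 * s$error_high)
})

test_that("group comparison reproduces reference ANOVA and Bonferroni", {
  set.seed(51)
  donors <- sprintf("D%02d", 1:12)
  groups <- rep(c("ctl", "dzA", "dzB"), each = 4)
  fr <- c(rnorm(4, 1e-3, 2e-4), rnorm(4, 3e-3, 2e-4), rnorm(4, 1.2e-3, 2e-4))
  summaries <- dplyr::bind_rows(lapply(seq_along(donors), function(i) {
    tibble::tibble(donor_id = donors[i], marker = "CD68",
                   cluster = c(1L, 2L),
                   fraction_base = c(fr[i], fr[i] / 10))
  }))
  grouping <- stats::setNames(groups, donors)
  cmp <- compare_groups(summaries, grouping)

  # ANOVA F and p agree with the pooled-variance reference fit
  ref <- stats::oneway.test(fr ~ factor(groups), var.equal = TRUE)
  a1 <- cmp$anova[cmp$anova$cluster == 1, ]
  expect_equal(a1$f_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(a1$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(a1$df_between, 2)
  expect_equal(a1$df_within, 9)

  # Bonferroni: adjusted = min(1, m * raw), m = 3 pairs; dominance holds
  expect_equal(cmp$n_comparisons, 3)
  expect_equal(cmp$pairwise$p_adj, pmin(1, 3 * cmp$pairwise$p_raw))
  expect_true(all(cmp$pairwise$p_adj >= cmp$pairwise$p_raw))
  expect_true(all(cmp$pairwise$p_adj <= 1))
  # against the stock adjustment routine on the same raw values
  pw1 <- cmp$pairwise[cmp$pairwise$cluster == 1, ]
  expect_equal(pw1$p_adj, stats::p.adjust(pw1$p_raw, "bonferroni", n = 3))

  # pairwise raw p agrees with a direct Welch test
  y1 <- fr[groups == "ctl"]; y2 <- fr[groups == "dzA"]
  want <- stats::t.test(y1, y2)$p.value
  got <- pw1$p_raw[pw1$group1 == "ctl" & pw1$group2 == "dzA"]
  expect_equal(got, want, tolerance = 1e-12)

  # tidy/glance accessors
  expect_identical(tidy(cmp), cmp$pairwise)
  expect_true(all(c("significant", "alpha") %in% names(glance(cmp))))
})

test_that("group comparison handles degenerate and invalid inputs", {
  summaries <- dplyr::bind_rows(lapply(sprintf("D%02d", 1:6), function(d) {
    tibble::tibble(donor_id = d, marker = "x", cluster = c(1L, 2L),
                   fraction_base = c(2e-3, 1e-4)) # identical everywhere
  }))
  grouping <- stats::setNames(rep(c("a", "b"), each = 3),
                              sprintf("D%02d", 1:6))
  cmp <- compare_groups(summaries, grouping)
  expect_true(all(cmp$anova$p_value == 1))
  expect_true(all(cmp$pairwise$stars == "ns"))

  # star thresholds on the adjusted p
  expect_equal(dabquant:::significance_stars(c(2e-1, 4e-2, 9e-3, 9e-4, 9e-5)),
               c("ns", "*", "**", "***", "****"))

  expect_error(compare_groups(summaries,
                              stats::setNames(rep("a", 6),
                                              sprintf("D%02d", 1:6))),
               "2 groups")
  grouping2 <- stats::setNames(c("a", rep("b", 5)), sprintf("D%02d", 1:6))
  expect_error(compare_groups(summaries, grouping2), "fewer than 2")
})
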