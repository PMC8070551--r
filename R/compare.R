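#' Compare donor groups by one-way ANOVA with Bonferroni post-hoc tests
#'
#' For each size cluster, runs a one-way ANOVA of the base-threshold
#' normalized fractions across disease groups, followed by all pairwise
#' two-sample t-tests with Bonferroni correction (adjusted p =
#' min(1, m * raw p), m = number of pairs). Pairwise tests are Welch by
#' default; `pool_var = TRUE` gives the classical equal-variance t.
#' Significance stars follow the usual legend: * p <= 0.05, ** p <= 0.01,
#' *** p <= 0.001, **** p <= 0.0001, on the adjusted p.
#'
#' Degenerate inputs (all fractions identical within and between groups)
#' carry no evidence of a difference and are reported as F = 0, p = 1.
#'
#' @param summaries a `donor_summary` tibble (row-bound over donors).
#' @param grouping named character vector or two-column data frame mapping
#'   `donor_id` to a group label.
#' @param alpha significance level (default 0.05).
#' @param pool_var use the pooled-variance t-test for pairwise comparisons.
#' @return A `group_comparison` object: list with `anova` (tibble:
#'   `cluster`, `df_between`, `df_within`, `f_statistic`, `p_value`),
#'   `pairwise` (tibble: `cluster`, `group1`, `group2`, `estimate1`,
#'   `estimate2`, `p_raw`, `p_adj`, `stars`), `alpha`, `n_comparisons`.
#' @export
compare_groups <- function(summaries, grouping, alpha = 0.05,
                           pool_var = FALSE) {
  if (is.data.frame(grouping)) {
    grouping <- setNames(as.character(grouping[[2]]),
                         as.character(grouping[[1]]))
  }
  df <- as_tibble(summaries) |>
    dplyr::mutate(group = unname(grouping[.data$donor_id]))
  if (anyNA(df$group)) {
    abort(sprintf("donors without group label: %s",
                  paste(unique(df$donor_id[is.na(df$group)]), collapse = ", ")))
  }
  sizes <- df |>
    dplyr::distinct(.data$donor_id, .data$group) |>
    dplyr::count(.data$group)
  if (nrow(sizes) < 2) abort("need at least 2 groups.")
  small <- sizes$group[sizes$n < 2]
  if (length(small) > 0) {
    abort(sprintf("group(s) with fewer than 2 donors: %s",
                  paste(small, collapse = ", ")))
  }
  groups <- sort(unique(df$group))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  m <- length(pairs)

  per_cluster <- lapply(sort(unique(df$cluster)), function(cl) {
    d <- df[df$cluster == cl, ]
    y <- d$fraction_base
    g <- factor(d$group, levels = groups)
    if (stats::var(y) < .Machine$double.eps) {
      an <- tibble(cluster = cl, df_between = length(groups) - 1L,
                   df_within = length(y) - length(groups),
                   f_statistic = 0, p_value = 1)
    } else {
      fit <- aov(y ~ g)
      s <- summary(fit)[[1]]
      an <- tibble(cluster = cl, df_between = s[1, "Df"],
                   df_within = s[2, "Df"],
                   f_statistic = s[1, "F value"], p_value = s[1, "Pr(>F)"])
    }
    pw <- purrr::map_dfr(pairs, function(pr) {
      y1 <- y[g == pr[1]]; y2 <- y[g == pr[2]]
      if (stats::var(c(y1, y2)) < .Machine$double.eps) {
        p_raw <- 1
      } else {
        p_raw <- t.test(y1, y2, var.equal = pool_var)$p.value
      }
      tibble(cluster = cl, group1 = pr[1], group2 = pr[2],
             estimate1 = mean(y1), estimate2 = mean(y2), p_raw = p_raw)
    })
    pw$p_adj <- pmin(1, m * pw$p_raw)
    pw$stars <- significance_stars(pw$p_adj)
    list(anova = an, pairwise = pw)
  })

  structure(
    list(anova = dplyr::bind_rows(purrr::map(per_cluster, "anova")),
         pairwise = dplyr::bind_rows(purrr::map(per_cluster, "pairwise")),
         alpha = alpha, n_comparisons = m),
    class = "group_comparison"
  )
}

significance_stars <- function(p) {
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 5e-2 ~ "*",
    TRUE ~ "ns"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d pairwise comparisons, alpha = %g\n",
              x$n_comparisons, x$alpha))
  cat("ANOVA per cluster:\n"); print(x$anova)
  cat("Bonferroni pairwise:\n"); print(x$pairwise)
  invisible(x)
}

#' @rdname compare_groups
#' @param x a `group_comparison` object.
#' @param ... unused.
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::mutate(x$anova,
                alpha = x$alpha,
                n_comparisons = x$n_comparisons,
                significant = .data$p_value <= x$alpha)
}
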