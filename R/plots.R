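#' Bar plot of donor-level normalized fractions with window error bars
#'
#' One bar per donor, faceted by cluster: bar height is the base-threshold
#' normalized area fraction, the error bar spans the minimum to maximum
#' fraction over the threshold window — the detection-method error, not a
#' biological spread.
#'
#' @param object a `donor_summary` tibble (row-bound over donors).
#' @param fill optional name of a column to map to bar fill (e.g. a group
#'   label column joined beforehand).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.donor_summary <- function(object, fill = NULL, ...) {
  df <- as_tibble(object)
  df$cluster_lab <- paste("Cluster", df$cluster)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$donor_id,
                                        y = .data$fraction_base))
  if (!is.null(fill)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data[[fill]]))
  } else {
    p <- p + ggplot2::geom_col(fill = "grey35")
  }
  p +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$error_low, ymax = .data$error_high),
      width = 0.3) +
    ggplot2::facet_wrap(~cluster_lab, scales = "free_y") +
    ggplot2::labs(x = "donor",
                  y = "segmented area / tissue area") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
plot.donor_summary <- function(x, ...) print(autoplot(x, ...))

#' Plot of group comparison results
#'
#' Group means of the base-threshold fractions with per-donor points,
#' faceted by cluster; the subtitle lists the ANOVA p-value per cluster.
#'
#' @param object a `group_comparison` object.
#' @param summaries the `donor_summary` tibble the comparison was fitted
#'   on.
#' @param grouping the same donor-to-group mapping.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, summaries, grouping, ...) {
  if (is.data.frame(grouping)) {
    grouping <- setNames(as.character(grouping[[2]]),
                         as.character(grouping[[1]]))
  }
  df <- as_tibble(summaries) |>
    dplyr::mutate(group = unname(grouping[.data$donor_id]),
                  cluster_lab = paste("Cluster", .data$cluster))
  lab <- paste(sprintf("cluster %d: p = %.3g", object$anova$cluster,
                       object$anova$p_value), collapse = "; ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = .data$fraction_base)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey70") +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::facet_wrap(~cluster_lab, scales = "free_y") +
    ggplot2::labs(x = "group", y = "segmented area / tissue area",
                  subtitle = paste("one-way ANOVA:", lab)) +
    ggplot2::theme_minimal()
}
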