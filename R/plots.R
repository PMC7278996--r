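#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point
#'   geom_pointrange facet_wrap labs scale_y_continuous
NULL

#' Plot category composition of a caller's variants
#'
#' Bar chart of the number of variants per reproducibility category.
#'
#' @param object A [categorize_all()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.category_assignment <- function(object, ...) {
  counts <- tibble(category = factor(1:4),
                   n = vapply(1:4, function(k) sum(object$category == k),
                              integer(1)))
  ggplot(counts, aes(x = .data$category, y = .data$n)) +
    geom_col(fill = "grey30") +
    labs(x = "Category", y = "Variants",
         title = paste0(attr(object, "caller"), " (",
                        attr(object, "mode"), " calls)"))
}

#' Plot Venn region sizes
#'
#' Bar chart of the seven region sizes of a three-set partition
#' (a quantitative stand-in for the Venn diagram).
#'
#' @param object A [venn_groups()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.venn_partition <- function(object, ...) {
  labs7 <- attr(object, "region_labels")
  counts <- tibble(
    region = factor(labs7, levels = labs7),
    n = vapply(1:7, function(r) sum(object$region == r), integer(1)))
  ggplot(counts, aes(x = .data$region, y = .data$n)) +
    geom_col(fill = "grey30") +
    labs(x = NULL, y = "Variants") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot saturation curves
#'
#' Metric values against subsampled read number; detection counts are
#' drawn per caller when present.
#'
#' @param object A [saturation_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saturation_curve <- function(object, ...) {
  if ("caller" %in% names(object)) {
    long <- pivot_longer(as_tibble(object),
                         any_of(c("n_detected", "n_category_12")),
                         names_to = "metric", values_to = "value")
    ggplot(long, aes(x = .data$n_reads, y = .data$value,
                     colour = .data$caller)) +
      geom_line() + geom_point() +
      facet_wrap(~metric, scales = "free_y") +
      labs(x = "Reads", y = "Variants")
  } else {
    long <- pivot_longer(as_tibble(object),
                         any_of(c("average_depth", "coverage_rate",
                                  "pct_regions_full", "pct_regions_zero",
                                  "on_target_rate")),
                         names_to = "metric", values_to = "value")
    ggplot(long, aes(x = .data$n_reads, y = .data$value)) +
      geom_line() + geom_point() +
      facet_wrap(~metric, scales = "free_y") +
      labs(x = "Reads", y = NULL)
  }
}

#' Plot per-variant VAF summaries
#'
#' Mean +/- SD of the variant allele frequency per variant (grouped by
#' caller when the summary was computed `by_caller`).
#'
#' @param summary A [vaf_summary()] result.
#' @return A ggplot object.
#' @export
plot_vaf_summary <- function(summary) {
  p <- ggplot(summary,
              aes(x = .data$key, y = .data$mean,
                  ymin = .data$mean - dplyr::coalesce(.data$sd, 0),
                  ymax = .data$mean + dplyr::coalesce(.data$sd, 0)))
  if ("caller" %in% names(summary)) {
    p <- p + geom_pointrange(aes(colour = .data$caller),
                             position = ggplot2::position_dodge(0.5))
  } else {
    p <- p + geom_pointrange()
  }
  p + labs(x = NULL, y = "VAF (fraction)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
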