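#' @import ggplot2
NULL

#' Plot normalized coverage along the genome for one sample
#'
#' Per-bin normalized copy number with optional call intervals shaded;
#' horizontal guides at integer copy states.
#'
#' @param coverage wide coverage tibble.
#' @param sample sample id to plot.
#' @param calls optional call tibble (`chrom`, `start`, `end`) to shade.
#' @return a ggplot object.
#' @export
plot_coverage <- function(coverage, sample, calls = NULL) {
  cm <- as_cov_matrix(coverage)
  df <- bind_cols(cm$meta, cn = cm$m[, sample])
  p <- ggplot(df, aes(x = (.data$start + .data$end) / 2, y = .data$cn)) +
    geom_hline(yintercept = 1:3, linetype = "dotted", colour = "grey60") +
    geom_point(size = 0.3, alpha = 0.6) +
    facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    labs(x = "position (bp)", y = "normalized copy number",
         title = sample) +
    theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    p <- p + geom_rect(data = calls,
                       aes(xmin = .data$start, xmax = .data$end),
                       ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
                       fill = "firebrick", alpha = 0.15)
  }
  p
}

#' Plot phased B-allele frequency for one sample
#'
#' Per-site phased BAF with optional imbalance segments overlaid.
#'
#' @param counts phased counts tibble.
#' @param sample sample id.
#' @param segments optional segment tibble from [segment_imbalance()].
#' @return a ggplot object.
#' @export
plot_baf <- function(counts, sample, segments = NULL) {
  df <- counts |>
    filter(.data$sample == !!sample) |>
    mutate(baf = .data$hap1_depth /
             (.data$hap1_depth + .data$hap2_depth))
  p <- ggplot(df, aes(x = .data$pos, y = .data$baf)) +
    geom_hline(yintercept = 0.5, linetype = "dotted", colour = "grey60") +
    geom_point(size = 0.3, alpha = 0.5) +
    facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    labs(x = "position (bp)", y = "phased BAF", title = sample) +
    theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    p <- p + geom_segment(data = segments,
                          aes(x = .data$start, xend = .data$end,
                              y = .data$baf, yend = .data$baf),
                          colour = "firebrick", linewidth = 1,
                          inherit.aes = FALSE)
  }
  p
}

#' Heatmap of polygenic-score z-scores across lines and traits
#'
#' @param profiles tibble from [adjust_and_normalize()].
#' @param outlier_sd z magnitude marked as outlier in the legend scale.
#' @return a ggplot object.
#' @export
plot_prs <- function(profiles, outlier_sd = 2) {
  ggplot(profiles, aes(x = .data$trait, y = .data$sample,
                       fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick",
                         limits = c(-2, 2) * outlier_sd,
                         oob = scales_squish) +
    labs(x = NULL, y = NULL, fill = "PRS z") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

# minimal squish to avoid a scales dependency at runtime
scales_squish <- function(x, range = c(0, 1)) pmin(pmax(x, range[1]), range[2])

#' Coefficient plot for a burden regression
#'
#' @param object a `burden_reg` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.burden_reg <- function(object, ...) {
  td <- generics::tidy(object) |> filter(.data$term != "(Intercept)")
  ggplot(td, aes(x = .data$estimate, y = .data$term)) +
    geom_vline(xintercept = 0, linetype = "dotted") +
    geom_pointrange(aes(xmin = .data$estimate - 1.96 * .data$std.error,
                        xmax = .data$estimate + 1.96 * .data$std.error)) +
    facet_wrap(~ .data$burden, scales = "free_x") +
    labs(x = "effect on burden per line", y = NULL) +
    theme_minimal()
}
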