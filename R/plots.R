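#' Plot a fragment-length distribution
#'
#' Histogram of fragment lengths, optionally faceted by sample.
#'
#' @param pop A [fragment_population()] (stacked populations work too).
#' @param binwidth Histogram bin width in bp.
#' @param max_bp Truncate the x axis at this length (HMW tails otherwise
#'   flatten the nucleosomal structure).
#' @return A ggplot object.
#' @export
plot_fragment_lengths <- function(pop, binwidth = 5, max_bp = 800) {
  assert_columns(pop, "length_bp", "a fragment population")
  df <- filter(as_tibble(pop), .data$length_bp <= max_bp)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$length_bp)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "Fragment length (bp)", y = "Fragments") +
    ggplot2::theme_minimal()
  if ("sample_id" %in% names(df) && length(unique(df$sample_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~sample_id, scales = "free_y")
  }
  p
}

#' @title Plot an electropherogram trace
#' @description Mass-density trace with dotted markers at the two amplicon
#'   cutoffs used by the molarity-ratio statistic.
#' @param object An `electropherogram`.
#' @param cutoffs Sizes (bp) to mark with dotted lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.electropherogram <- function(object, cutoffs = c(106, 612), ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$size_bp, y = .data$mass_density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = cutoffs, linetype = "dotted") +
    ggplot2::labs(x = "Size (bp)", y = "Mass density") +
    ggplot2::theme_minimal()
}

#' Plot short/long copy estimates per sample
#'
#' Dot-and-line display of paired short- and long-amplicon copies per ng
#' for each sample and region, with a dashed line at the theoretical
#' single-copy content of 1 ng human genomic DNA (~303 copies).
#'
#' @param summaries Output of [fragmentation_summary()].
#' @param reference_copies Dashed reference line (copies/ng).
#' @return A ggplot object.
#' @export
plot_copies_estimates <- function(summaries, reference_copies = 303) {
  assert_columns(summaries, c("sample_id", "region_label",
                              "short_copies_per_ng", "long_copies_per_ng"),
                 "a fragmentation summary")
  long <- summaries |>
    tidyr::pivot_longer(c("short_copies_per_ng", "long_copies_per_ng"),
                        names_to = "target", values_to = "copies_per_ng") |>
    mutate(target = ifelse(.data$target == "short_copies_per_ng",
                           "short", "long"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target,
                                     y = .data$copies_per_ng,
                                     group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = reference_copies,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~region_label) +
    ggplot2::labs(x = NULL, y = "Copies per ng") +
    ggplot2::theme_minimal()
}

#' Plot qPCR contamination score against AEF molarity ratio
#'
#' Log-log scatter of the two orthogonal HMW-contamination readouts on
#' matched samples.
#'
#' @param df Tibble with columns `percent_hmw` and `molarity_ratio`.
#' @return A ggplot object.
#' @export
plot_score_vs_ratio <- function(df) {
  assert_columns(df, c("percent_hmw", "molarity_ratio"),
                 "a matched score/ratio table")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$molarity_ratio,
                                   y = .data$percent_hmw)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "AEF molarity ratio (>106 bp / >612 bp)",
                  y = "qPCR contamination score (%)") +
    ggplot2::theme_minimal()
}
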