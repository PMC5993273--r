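#' Histogram of laterality indices
#'
#' Plots the LI distribution of a per-individual results table, filled by
#' bias class, optionally faceted by a grouping column such as sex. A
#' clearly two-humped histogram (left- and right-biased animals with few
#' near zero) is the visual signature of individual-level laterality
#' without a population-level bias.
#'
#' @param results A tibble from [assess_laterality()].
#' @param by Optional tidy-eval column to facet by (e.g. `sex`).
#' @param binwidth Histogram bin width in LI points.
#' @return A ggplot object.
#' @examples
#' plot_li_distribution(assess_laterality(focal_horses()), by = sex)
#' @export
plot_li_distribution <- function(results, by = NULL, binwidth = 20) {
  p <- ggplot2::ggplot(results, ggplot2::aes(x = .data$li,
                                             fill = .data$classification)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_x_continuous(limits = c(-105, 105)) +
    ggplot2::labs(x = "Laterality index (negative = left bias)",
                  y = "Animals", fill = "Classification") +
    ggplot2::theme_minimal()
  if (!rlang::quo_is_null(rlang::enquo(by))) {
    p <- p + ggplot2::facet_wrap(rlang::enquo(by))
  }
  p
}

#' @rdname plot_li_distribution
#' @param object A `laterality_results` tibble.
#' @param ... Passed to [plot_li_distribution()].
#' @export
autoplot.laterality_results <- function(object, ...) {
  plot_li_distribution(object, ...)
}
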