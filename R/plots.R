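#' Plot an aligned average trace
#'
#' Mean +/- SD ribbon per channel against time from the alignment landmark.
#'
#' @param avg an `aligned_average` tibble from [align_traces()].
#' @return a ggplot object.
#' @export
plot_aligned_average <- function(avg) {
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$time, y = .data$mean,
                                    color = .data$channel,
                                    fill = .data$channel)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                                      ymax = pmin(1, .data$mean + .data$sd)),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from landmark (s)",
                  y = "normalized fluorescence") +
    ggplot2::theme_classic()
}

#' Scatter plot of per-cell capture fractions by condition
#'
#' Points per cell with mean (thick) and mean +/- SD (thin) horizontal bars,
#' the standard presentation of the numerical capture assay.
#'
#' @param results tibble from [capture_results_table()] (QC-passing cells
#'   are plotted; failures are dropped with a message).
#' @return a ggplot object.
#' @export
plot_capture_scatter <- function(results) {
  if (any(!results$qc_pass)) {
    message(sum(!results$qc_pass), " cell(s) excluded by the 65% QC rule")
    results <- results[results$qc_pass, , drop = FALSE]
  }
  summ <- summarize_scatter(split(results$capture_fraction, results$condition))
  ggplot2::ggplot(results, ggplot2::aes(x = .data$condition,
                                        y = .data$capture_fraction)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    ggplot2::geom_errorbar(data = summ,
                           ggplot2::aes(x = .data$group, y = NULL,
                                        ymin = .data$mean, ymax = .data$mean),
                           width = 0.45, linewidth = 1.2) +
    ggplot2::geom_errorbar(data = summ,
                           ggplot2::aes(x = .data$group, y = NULL,
                                        ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3, linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "capture fraction") +
    ggplot2::theme_classic()
}

#' Stacked category-fraction bars
#'
#' @param tab a `category_table` from [tabulate_categories()].
#' @return a ggplot object.
#' @export
plot_category_fractions <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$condition, y = .data$fraction,
                                    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of cells") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 .data
NULL
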