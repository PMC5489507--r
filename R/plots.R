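#' Plot the distribution of evaluated cooperation levels
#'
#' Histogram (per evaluation mode) of independent equilibrium evaluations of
#' one structure, visualizing the fitness noise the optimizer must survive.
#'
#' @param samples A tibble from [run_distribution_study()].
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_distribution <- function(samples, bins = 30L) {
  ggplot2::ggplot(samples, ggplot2::aes(x = .data$coop)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", color = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$mode)) +
    ggplot2::labs(x = "evaluated cooperation level", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot an optimization trajectory
#'
#' @param result An `mlea_result`.
#' @return A ggplot object of the best mean fitness per generation.
#' @export
plot_trajectory <- function(result) {
  ggplot2::ggplot(tidy(result),
                  ggplot2::aes(x = .data$generation, y = .data$best_avg)) +
    ggplot2::geom_line(color = "grey20") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generation",
                  y = sprintf("best %s (avg)", result$objective)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_trajectory
#' @param object An `mlea_result`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.mlea_result <- function(object, ...) {
  plot_trajectory(object)
}

#' @export
ggplot2::autoplot

#' Plot a variant comparison
#'
#' Ranges (segments) and means (points) of post-hoc cooperation scores per
#' variant, alongside the initial structures' mean.
#'
#' @param results A tibble from [run_comparison()].
#' @return A ggplot object.
#' @export
plot_comparison <- function(results) {
  smry <- comparison_summary(results)
  ggplot2::ggplot(smry, ggplot2::aes(x = .data$variant)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$min_optimized,
                                         ymax = .data$max_optimized),
                            color = "grey60", linewidth = 4) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_optimized), size = 2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$mean_initial),
                        linetype = "dashed", color = "grey30") +
    ggplot2::labs(x = "optimizer variant", y = "cooperation level") +
    ggplot2::theme_minimal()
}
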