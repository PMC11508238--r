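#' Plot per-frame counts, optionally against ground truth
#'
#' @param counts Count tibble (`frame`, `patient`, `clinician`, `visitor`).
#' @param truth Optional ground-truth count tibble drawn as a reference line.
#' @return A ggplot object, faceted by category.
#' @export
plot_counts <- function(counts, truth = NULL) {
  long <- function(x, what) {
    tidyr::pivot_longer(x, dplyr::all_of(ICU_CATEGORIES),
                        names_to = "category", values_to = "count") %>%
      mutate(series = what)
  }
  df <- long(counts, "predicted")
  if (!is.null(truth)) df <- bind_rows(df, long(truth, "truth"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$count,
                                   colour = .data$series)) +
    ggplot2::geom_step(alpha = 0.8) +
    ggplot2::facet_wrap(~ factor(category, ICU_CATEGORIES), ncol = 1) +
    ggplot2::labs(x = "frame (1 fps)", y = "people counted", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname icucount-autoplot
#' @method autoplot icu_benchmark
#' @export
autoplot.icu_benchmark <- function(object, metric = "mae", ...) {
  df <- filter(glance(object), .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$method, c("single", "multi", "tracking")),
    y = .data$mean, fill = .data$method)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::facet_wrap(~ factor(category, ICU_CATEGORIES)) +
    ggplot2::labs(x = NULL, y = paste("mean", metric, "± sd")) +
    ggplot2::theme_minimal()
}

#' Autoplot methods for benchmark and sweep reports
#'
#' `autoplot()` on an `icu_benchmark` draws the per-method metric bars with
#' seed-to-seed standard deviations; on an `icu_sweep` it draws the metric
#' against window size per category.
#'
#' @param object Benchmark or sweep object.
#' @param metric Which counting metric to draw (`"mae"`, `"accuracy"`, ...).
#' @param ... Unused.
#' @return A ggplot object.
#' @name icucount-autoplot
#' @method autoplot icu_sweep
#' @export
autoplot.icu_sweep <- function(object, metric = "accuracy", ...) {
  df <- filter(glance(object), .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$mean,
                                   colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window size F (frames)", y = paste("mean", metric),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot grouped occupancy durations
#'
#' Bar chart of mean presence duration per delirium group for the moving
#' categories (clinician, visitor).
#'
#' @param groups Output of [group_durations()].
#' @return A ggplot object.
#' @export
plot_occupancy <- function(groups) {
  df <- filter(groups, .data$category != "patient", !is.na(.data$mean_duration_min))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean_duration_min,
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean presence (min / 30-min window)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
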