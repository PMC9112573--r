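#' @importFrom ggplot2 ggplot aes geom_point geom_errorbarh geom_col
#'   facet_wrap labs theme_minimal autoplot coord_flip geom_abline
#'   geom_histogram position_dodge
#' @export
ggplot2::autoplot

#' Forest plot of a metric report
#'
#' @param report A `metric_report` tibble (from [evaluate_base_learners()],
#'   [evaluate_meta_learners()] or `tidy()` on a run).
#' @param metrics Metrics to show (default MAE and AUC).
#' @return A ggplot object.
#' @export
plot_metric_report <- function(report, metrics = c("MAE", "AUC")) {
  dat <- report[report$metric %in% metrics, , drop = FALSE]
  ggplot(dat, aes(x = .data$estimate, y = .data$model)) +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_point(size = 2) +
    facet_wrap(~metric, scales = "free_x") +
    labs(x = "estimate (bootstrap mean, 95% percentile interval)",
         y = NULL) +
    theme_minimal()
}

#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) plot_metric_report(object, ...)

#' Bar chart of permutation feature importances
#'
#' @param record An `importance_record` tibble.
#' @param top_n Show the `top_n` most important features per model.
#' @return A ggplot object.
#' @export
plot_importance <- function(record, top_n = 15L) {
  dat <- record |>
    group_by(.data$model) |>
    arrange(dplyr::desc(.data$pct_change), .by_group = TRUE) |>
    slice_head(n = top_n) |>
    ungroup()
  ggplot(dat, aes(x = stats::reorder(.data$feature, .data$pct_change),
                  y = .data$pct_change)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~model, scales = "free") +
    labs(x = NULL,
         y = sprintf("mean %% change in %s under permutation",
                     record$metric[1L])) +
    theme_minimal()
}

#' @method autoplot importance_record
#' @export
autoplot.importance_record <- function(object, ...) plot_importance(object, ...)

#' Per-region metric dot plot of an internal-external validation report
#'
#' @param report A `region_report` from [internal_external_cv()].
#' @param metric Metric to display (default the report's first).
#' @return A ggplot object.
#' @export
plot_region_report <- function(report, metric = NULL) {
  metric <- metric %||% report$metric[1L]
  dat <- report[report$metric == metric, , drop = FALSE]
  ggplot(dat, aes(x = .data$value, y = .data$region,
                  shape = .data$region == "(average)")) +
    geom_point(size = 2) +
    facet_wrap(~model) +
    ggplot2::guides(shape = "none") +
    labs(x = metric, y = NULL) +
    theme_minimal()
}

#' @method autoplot region_report
#' @export
autoplot.region_report <- function(object, ...) plot_region_report(object, ...)
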