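#' Group x time trajectories of a metric
#'
#' Mean and standard-error trajectories across timepoints, one line per
#' group — the standard way to display the group-by-time structure the
#' mixed ANOVA tests.
#'
#' @param data Long tibble with columns `group`, `timepoint`, `value` (e.g.
#'   a filtered [metric_auc()] table).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_metric_trajectories <- function(data, title = NULL) {
  summ <- data |>
    dplyr::group_by(.data$group, .data$timepoint) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                     colour = .data$group,
                                     group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1) +
    ggplot2::labs(x = NULL, y = "metric (mean ± SE)", title = title) +
    ggplot2::theme_minimal()
}

#' Coupling scores by group and timepoint
#'
#' @param coupling Tibble from [coupling_table()] (columns `group`,
#'   `timepoint`, `r`).
#' @return A ggplot object.
#' @export
plot_coupling <- function(coupling) {
  ggplot2::ggplot(coupling, ggplot2::aes(x = .data$timepoint, y = .data$r,
                                         fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "FC-SC coupling (Pearson r)") +
    ggplot2::theme_minimal()
}

#' Global metrics across the density sweep
#'
#' @param metrics Long table from [study_metrics()]; global rows (node `NA`)
#'   for one metric are averaged per group x timepoint at each density.
#' @param metric Which global metric to draw (e.g. `"strength"`).
#' @return A ggplot object.
#' @export
plot_density_sweep <- function(metrics, metric = "strength") {
  d <- metrics |>
    dplyr::filter(is.na(.data$node), .data$metric == !!metric) |>
    dplyr::group_by(.data$group, .data$timepoint, .data$modality,
                    .data$density) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$density, y = .data$value,
                                  colour = .data$group,
                                  linetype = .data$timepoint)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$modality), scales = "free") +
    ggplot2::labs(x = "connection density", y = metric) +
    ggplot2::theme_minimal()
}

#' @rdname rm_anova
#' @param object An `lc_rm_anova` object.
#' @export
autoplot.lc_rm_anova <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$statistic)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("p = %.3g", .data$p.value)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "F statistic") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
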