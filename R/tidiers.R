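#' Tidy a single run
#'
#' One row per elimination level with the surviving cluster and feature
#' counts and the seven held-out metrics.
#'
#' @param x An `rceife_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rceife_run
#' @export
tidy.rceife_run <- function(x, ...) {
  x$per_level
}

#' Glance at a single run
#'
#' The final-level row: the readout level (last schedule element), its
#' feature count and metrics.
#'
#' @inheritParams tidy.rceife_run
#' @return A one-row tibble.
#' @method glance rceife_run
#' @export
glance.rceife_run <- function(x, ...) {
  dplyr::slice_tail(x$per_level, n = 1L)
}

#' Tidy an aggregate
#'
#' Long per-level statistics: one row per (level, metric) with mean, std and
#' the number of repetitions where the metric was defined.
#'
#' @param x An `rceife_agg` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rceife_agg
#' @export
tidy.rceife_agg <- function(x, ...) {
  x$per_level_stats
}

#' Glance at an aggregate
#'
#' One wide row for the final readout level: mean AUC, mean accuracy, mean
#' kappa, mean surviving feature count and the repetition count.
#'
#' @inheritParams tidy.rceife_agg
#' @return A one-row tibble.
#' @method glance rceife_agg
#' @export
glance.rceife_agg <- function(x, ...) {
  final <- min(x$per_level_stats$level)
  stats <- dplyr::filter(x$per_level_stats, .data$level == final)
  pick <- function(m) stats$mean[stats$metric == m]
  tibble::tibble(
    final_level = final,
    mean_auc = pick("auc"),
    mean_accuracy = pick("accuracy"),
    mean_kappa = pick("kappa"),
    mean_n_features = pick("n_features"),
    n_repeats = x$n_repeats
  )
}

#' Plot metrics across elimination levels
#'
#' Mean metric value per level with a +/- one standard deviation ribbon,
#' levels decreasing left to right so the elimination trajectory reads in
#' run order.
#'
#' @param object An `rceife_agg` object.
#' @param metrics Metrics to show (default accuracy and AUC).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rceife_agg
#' @export
autoplot.rceife_agg <- function(object, metrics = c("accuracy", "auc"), ...) {
  stats <- dplyr::filter(object$per_level_stats, .data$metric %in% metrics)
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$level, y = .data$mean,
                                      colour = .data$metric, fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$std,
                                      ymax = .data$mean + .data$std),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "clusters remaining", y = "held-out metric (mean ± sd)") +
    ggplot2::theme_minimal()
}

#' Plot a single run's per-level metrics
#'
#' @param object An `rceife_run` object.
#' @param metrics Metrics to show (default accuracy and AUC).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rceife_run
#' @export
autoplot.rceife_run <- function(object, metrics = c("accuracy", "auc"), ...) {
  long <- tidyr::pivot_longer(object$per_level, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "clusters remaining", y = "held-out metric") +
    ggplot2::theme_minimal()
}

#' Plot the head of the survival ranking
#'
#' Horizontal bar chart of the top-`n` features by survival score.
#'
#' @param aggregate An `rceife_agg` object.
#' @param n Number of features to show (default 20).
#' @return A ggplot object.
#' @export
plot_ranking <- function(aggregate, n = 20L) {
  top <- head(aggregate$ranking, n)
  ggplot2::ggplot(top, ggplot2::aes(x = .data$survival_score,
                                    y = stats::reorder(.data$feature_id,
                                                       .data$survival_score))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "survival score (levels survived, summed over runs)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
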