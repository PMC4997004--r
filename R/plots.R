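#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the combination grid
#'
#' Cross-validated accuracy of every (timeslot, method, family)
#' combination, pooled over users and scales: one box per timeslot and
#' family, faceted by selection method.
#'
#' @param object A `mood_training`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot mood_training
#' @export
autoplot.mood_training <- function(object, ...) {
  df <- dplyr::filter(object$results, !is.na(.data$accuracy))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$timeslot), y = .data$accuracy, fill = .data$family
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(
      x = "timeslot width (h)", y = "cross-validated accuracy",
      fill = "classifier"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-user evaluation accuracy
#'
#' @param object A `mood_evaluation`.
#' @param ... Ignored.
#' @return A ggplot: per-user predictive accuracy with the cohort mean.
#' @method autoplot mood_evaluation
#' @export
autoplot.mood_evaluation <- function(object, ...) {
  df <- dplyr::filter(object$per_user, !is.na(.data$accuracy))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$user_id, .data$accuracy), y = .data$accuracy
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(
      yintercept = object$cohort$mean_accuracy, linetype = 2
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "predictive accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Plot a wrapper search trajectory
#'
#' @param object A `mood_selection` from [greedy_select()].
#' @param ... Ignored.
#' @return A ggplot of the scorer value along the search, or the per-level
#'   P values for filter selections.
#' @method autoplot mood_selection
#' @export
autoplot.mood_selection <- function(object, ...) {
  if (!is.null(object$trajectory)) {
    ggplot2::ggplot(object$trajectory, ggplot2::aes(.data$step, .data$score)) +
      ggplot2::geom_step() +
      ggplot2::geom_point(ggplot2::aes(color = .data$action)) +
      ggplot2::labs(
        x = "search step", y = "cross-validated accuracy",
        title = object$method
      ) +
      ggplot2::theme_minimal()
  } else {
    df <- tidyr::pivot_longer(object$p_values, c("p_level1", "p_level2"),
      names_to = "level", values_to = "p"
    )
    ggplot2::ggplot(
      dplyr::filter(df, !is.na(.data$p)),
      ggplot2::aes(.data$p, stats::reorder(.data$feature, -.data$p), color = .data$level)
    ) +
      ggplot2::geom_point() +
      ggplot2::geom_vline(xintercept = 0.05, linetype = 2) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "P value", y = NULL, title = object$method) +
      ggplot2::theme_minimal()
  }
}
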