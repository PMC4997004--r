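#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a feature selection result
#'
#' @param x A `mood_selection`.
#' @param ... Ignored.
#' @return Tibble with one row per available feature: `feature`,
#'   `selected`, and per-level P values for the filter methods.
#' @method tidy mood_selection
#' @export
tidy.mood_selection <- function(x, ...) {
  if (!is.null(x$p_values)) {
    dplyr::mutate(x$p_values, selected = .data$feature %in% x$selected)
  } else {
    tibble::tibble(feature = x$selected, selected = TRUE)
  }
}

#' @rdname tidy.mood_selection
#' @method glance mood_selection
#' @export
glance.mood_selection <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_selected = length(x$selected), score = x$score
  )
}

#' Tidy a combination-grid training result
#'
#' @param x A `mood_training`.
#' @param ... Ignored.
#' @return The full combination results tibble (one row per combination
#'   per user and scale).
#' @method tidy mood_training
#' @export
tidy.mood_training <- function(x, ...) x$results

#' @rdname tidy.mood_training
#' @method glance mood_training
#' @export
glance.mood_training <- function(x, ...) {
  tibble::tibble(
    n_users = length(x$users),
    n_combos = nrow(dplyr::distinct(
      x$results, .data$timeslot, .data$method, .data$family
    )),
    timeslot = x$choice$timeslot,
    method = x$choice$method,
    family = x$choice$family,
    mean_accuracy = x$choice$mean_accuracy
  )
}

#' Tidy an evaluation summary
#'
#' @param x A `mood_evaluation`.
#' @param ... Ignored.
#' @return The per-user accounting tibble.
#' @method tidy mood_evaluation
#' @export
tidy.mood_evaluation <- function(x, ...) x$per_user

#' @rdname tidy.mood_evaluation
#' @method glance mood_evaluation
#' @export
glance.mood_evaluation <- function(x, ...) x$cohort

#' @method glance mood_model
#' @export
glance.mood_model <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_features = length(x$feature_keys),
    n_classes = length(x$classes),
    constant = x$constant
  )
}
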