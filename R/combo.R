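#' Detection-classifier selection by rank product
#'
#' Every candidate detection classifier is one combination of timeslot
#' width, feature-selection method and classifier family. All combinations
#' are evaluated per user and scale by stratified cross-validated accuracy,
#' and then reduced in two stages:
#'
#' 1. within each selection method, combinations of (timeslot, family) are
#'    scored by the rank product of their accuracy ranks across all
#'    (user, scale) contexts — rank aggregation depends only on rank order,
#'    so outlying accuracy values carry no extra weight;
#' 2. among the five per-method winners, the final choice maximizes mean
#'    accuracy over the three scales (averaged over users).
#'
#' @name combo-selection
NULL

#' Build design matrices for one user over all candidate timeslots
#'
#' @param events Training events tibble for one user.
#' @param tags Training emotion tags for the same user.
#' @param widths Timeslot widths in hours (default [timeslot_widths()]).
#' @param top_k Top-app count for the usage type list.
#' @return Named list (width as name) of `mood_design` objects sharing one
#'   usage type list.
#' @export
prepare_user_designs <- function(events, tags, widths = timeslot_widths(), top_k = 10) {
  types <- usage_types_for_user(events, top_k)
  out <- lapply(widths, function(w) {
    build_design_matrix(events, tags, w, usage_types = types)
  })
  names(out) <- as.character(widths)
  out
}

#' Evaluate the full combination grid
#'
#' Exhaustive grid of timeslot x selection method x classifier family per
#' (user, scale). Filter selections (the two t-test variants) are computed
#' once per (user, scale, timeslot) and shared across families; wrapper
#' selections use each family as their own scorer, and their recorded
#' accuracy is the best score reached by the search (the same
#' cross-validation the scorer uses). A selection failure is recorded as a
#' missing accuracy and flagged rather than aborting the grid.
#'
#' @param designs Named list: `user_id -> (named list: width -> mood_design)`,
#'   as built by [prepare_user_designs()].
#' @param methods Selection methods (default all five).
#' @param families Classifier families (default all four).
#' @param folds Cross-validation folds (default 5).
#' @param seed Master seed; fold seeds are derived per (user, scale,
#'   timeslot) so every method/family pair competes on identical folds.
#' @return Tibble with one row per combination per (user, scale): columns
#'   `user`, `scale`, `timeslot`, `method`, `family`, `accuracy`,
#'   `n_features`, `flagged`.
#' @export
evaluate_all_combos <- function(designs, methods = selection_methods(),
                                families = classifier_families(),
                                folds = 5, seed = 1) {
  rows <- list()
  for (user in names(designs)) {
    for (w_name in names(designs[[user]])) {
      design <- designs[[user]][[w_name]]
      w <- design$width_hours
      X <- design$features
      for (scale in emotion_scales()) {
        y <- design$labels[[scale]]
        fold_seed <- derive_seed(seed, paste(user, scale, w_name, sep = "/"))
        for (method in methods) {
          # one selection per (user, scale, timeslot, method), shared across
          # families; the wrappers score with the fixed naive-Bayes scorer
          sel <- tryCatch(
            suppressWarnings(
              select_features(X, y, method, "naive_bayes", folds, fold_seed)
            ),
            error = function(e) e
          )
          for (family in families) {
            if (inherits(sel, "error")) {
              acc <- NA_real_
              nf <- NA_integer_
            } else if (family == "naive_bayes" && !is.na(sel$score)) {
              acc <- sel$score
              nf <- length(sel$selected)
            } else {
              acc <- suppressWarnings(cross_validated_accuracy(
                family, X[, sel$selected, drop = FALSE], y, folds, fold_seed
              ))
              nf <- length(sel$selected)
            }
            rows[[length(rows) + 1]] <- tibble::tibble(
              user = user, scale = scale, timeslot = w, method = method,
              family = family, accuracy = acc, n_features = nf,
              flagged = is.na(acc)
            )
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Rank-product scores for combinations
#'
#' Within each (user, scale) context, combinations are ranked by accuracy
#' descending (rank 1 best; ties get the average rank; a missing accuracy
#' gets the worst rank in its context). The score of a combination is the
#' geometric mean of its ranks across contexts — geometric mean rather than
#' the raw product, so scores are comparable across context counts.
#'
#' @param results Combo results tibble from [evaluate_all_combos()].
#' @return Tibble `timeslot`, `method`, `family`, `rank_product`,
#'   `n_contexts`, sorted ascending by score (best first).
#' @export
rank_product <- function(results) {
  if (nrow(results) == 0) {
    abort("no combination results to rank", class = "moodphone_validation_error")
  }
  results %>%
    dplyr::group_by(.data$user, .data$scale) %>%
    dplyr::mutate(
      rank = rank(-dplyr::coalesce(.data$accuracy, -Inf), ties.method = "average")
    ) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$timeslot, .data$method, .data$family) %>%
    dplyr::summarise(
      rank_product = exp(mean(log(.data$rank))),
      n_contexts = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$rank_product, .data$timeslot, .data$method, .data$family)
}

#' Choose the deployed combination
#'
#' Stage 1: for each selection method, the (timeslot, family) pair with the
#' smallest rank-product score across (user, scale) contexts wins (ties:
#' smaller timeslot, then family name order). Stage 2: among the per-method
#' winners, the final choice maximizes mean accuracy over the three scales
#' averaged over users (ties: smaller timeslot, then method name order).
#'
#' @param results Combo results tibble from [evaluate_all_combos()].
#' @return A list of class `mood_combo_choice`: `timeslot`, `method`,
#'   `family`, `mean_accuracy`, plus the per-method `winners` tibble.
#' @export
select_final <- function(results) {
  winners <- results %>%
    dplyr::group_by(.data$method) %>%
    dplyr::group_modify(function(df, key) {
      rp <- rank_product(dplyr::mutate(df, method = key$method))
      rp %>%
        dplyr::arrange(.data$rank_product, .data$timeslot, .data$family) %>%
        utils::head(1) %>%
        dplyr::select(-"method")
    }) %>%
    dplyr::ungroup()
  mean_acc <- results %>%
    dplyr::inner_join(winners, by = c("timeslot", "method", "family")) %>%
    dplyr::group_by(.data$method, .data$timeslot, .data$family) %>%
    dplyr::summarise(mean_accuracy = mean(.data$accuracy, na.rm = TRUE), .groups = "drop")
  winners <- dplyr::left_join(winners, mean_acc,
    by = c("method", "timeslot", "family")
  ) %>%
    dplyr::arrange(
      dplyr::desc(.data$mean_accuracy), .data$timeslot, .data$method
    )
  best <- winners[1, ]
  structure(
    list(
      timeslot = best$timeslot, method = best$method, family = best$family,
      mean_accuracy = best$mean_accuracy, winners = winners
    ),
    class = "mood_combo_choice"
  )
}

#' @export
print.mood_combo_choice <- function(x, ...) {
  cat(sprintf(
    "<mood_combo_choice> %.1f h timeslot, %s selection, %s classifier (mean CV accuracy %.3f)\n",
    x$timeslot, x$method, x$family, x$mean_accuracy
  ))
  invisible(x)
}
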