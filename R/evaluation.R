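#' Prospective evaluation protocol
#'
#' During the evaluation phase the deployed personalized classifier makes a
#' prediction of the three emotion categories every 2 hours from 11:00 to
#' 23:00 (7 per day). The user may respond by correcting the three VAS
#' sliders; a responded prediction is successful only if all three
#' corrected ratings fall in the predicted categories. Accounting follows
#' the published presentation: per-user predictive accuracy is
#' `100 * successes / responses` (half-up, 2 decimals), the cohort accuracy
#' is the unweighted mean of per-user accuracies, and the pooled rate
#' (total successes / total responses) is reported alongside.
#'
#' @name evaluation-protocol
NULL

#' Daily prediction schedule
#'
#' @param day A `Date` (or string coercible to one).
#' @return POSIXct vector (UTC) of the 7 prediction times: 11:00, 13:00,
#'   ..., 23:00.
#' @export
schedule_predictions <- function(day) {
  day <- as.Date(day)
  as.POSIXct(day, tz = "UTC") + 3600 * seq(11, 23, by = 2)
}

#' Judge one prediction against the corrected ratings
#'
#' @param predicted Character/factor vector of 3 predicted categories, in
#'   scale order (depression, anxiety, stress).
#' @param corrected Numeric vector of 3 corrected VAS values.
#' @return `TRUE` iff all three corrected categories equal the predictions.
#' @export
judge_prediction <- function(predicted, corrected) {
  all(as.character(vas_categorize(corrected)) == as.character(predicted))
}

#' Summarize a prediction log
#'
#' @param records Tibble with one row per prediction made: `user_id`,
#'   `timestamp`, `responded` (logical), `success` (logical, `NA` when not
#'   responded).
#' @return A `mood_evaluation` object: list with `per_user` (user, days,
#'   n_responded, n_success, accuracy) and `cohort` (one-row tibble with
#'   totals, feedback rate, pooled and unweighted-mean accuracy).
#' @export
summarize_evaluation <- function(records) {
  per_user <- records %>%
    dplyr::group_by(user_id = .data$user_id) %>%
    dplyr::summarise(
      days = dplyr::n_distinct(as.Date(.data$timestamp)),
      n_responded = sum(.data$responded),
      n_success = sum(.data$success[.data$responded]),
      .groups = "drop"
    )
  summarize_evaluation_counts(per_user, n_made = nrow(records))
}

#' Summarize evaluation accounting from per-user counts
#'
#' Entry point for count data (for example a published accounting table):
#' only (responses, successes) pairs are needed for the accuracies.
#'
#' @param counts Tibble with columns `user_id`, `n_responded`, `n_success`
#'   and optionally `days`.
#' @param n_made Total number of predictions made (for the feedback rate);
#'   `NA` if unknown.
#' @return A `mood_evaluation` object (see [summarize_evaluation()]).
#' @export
summarize_evaluation_counts <- function(counts, n_made = NA_integer_) {
  per_user <- tibble::as_tibble(counts)
  if (!"days" %in% names(per_user)) per_user$days <- NA_integer_
  zero <- per_user$n_responded == 0
  if (any(zero)) {
    warn(sprintf(
      "%d user(s) with zero responses excluded from the cohort mean",
      sum(zero)
    ))
  }
  per_user <- per_user %>%
    dplyr::mutate(
      accuracy = ifelse(.data$n_responded > 0,
        round_half_up(100 * .data$n_success / .data$n_responded, 2), NA_real_
      )
    ) %>%
    dplyr::select("user_id", "days", "n_responded", "n_success", "accuracy")
  cohort <- tibble::tibble(
    n_users = nrow(per_user),
    n_made = n_made,
    n_responded = sum(per_user$n_responded),
    n_success = sum(per_user$n_success),
    feedback_rate = if (!is.na(n_made) && n_made > 0) {
      round_half_up(100 * sum(per_user$n_responded) / n_made, 2)
    } else {
      NA_real_
    },
    pooled_accuracy = round_half_up(
      100 * sum(per_user$n_success) / sum(per_user$n_responded), 2
    ),
    mean_accuracy = round_half_up(mean(per_user$accuracy[!zero]), 2)
  )
  structure(list(per_user = per_user, cohort = cohort), class = "mood_evaluation")
}

#' @export
print.mood_evaluation <- function(x, ...) {
  c <- x$cohort
  cat(sprintf(
    "<mood_evaluation> %d users, %d/%d successful responses (pooled %.2f%%, mean %.2f%%)\n",
    c$n_users, c$n_success, c$n_responded, c$pooled_accuracy, c$mean_accuracy
  ))
  invisible(x)
}

#' Multiple-linear-regression benchmark
#'
#' Ordinary least squares of the raw VAS value on the usage features, fit
#' per scale; a prediction is the fitted value clipped to `[0, 100]` and
#' then categorized. Rank-deficient designs fall back to the usual
#' pivoting solution with a warning.
#'
#' @param x Feature matrix (training tags x features).
#' @param vas Tibble of raw VAS values (`depression`, `anxiety`, `stress`).
#' @return A `mood_linear_benchmark` with a [predict()] method returning a
#'   tibble of per-scale categories.
#' @export
benchmark_linear <- function(x, vas) {
  X <- as_feature_matrix(x)
  fits <- lapply(emotion_scales(), function(scale) {
    df <- rpart_frame(X)
    df$.y <- vas[[scale]]
    fit <- stats::lm(.y ~ ., df)
    if (anyNA(stats::coef(fit))) {
      warn(sprintf("rank-deficient design for %s: pivoted least squares", scale))
    }
    fit
  })
  names(fits) <- emotion_scales()
  structure(list(fits = fits, feature_keys = colnames(X)),
    class = "mood_linear_benchmark"
  )
}

#' @export
predict.mood_linear_benchmark <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$feature_keys)
  df <- rpart_frame(X)
  out <- lapply(object$fits, function(fit) {
    yhat <- suppressWarnings(unname(stats::predict(fit, df)))
    vas_categorize(pmin(pmax(yhat, 0), 100))
  })
  tibble::as_tibble(out)
}

#' General-guess benchmark
#'
#' Always predicts the user's most frequent training category per scale;
#' ties go to the lower category.
#'
#' @param labels Tibble of training category labels per scale (as in a
#'   `mood_design`).
#' @return A `mood_guess_benchmark` with a [predict()] method.
#' @export
benchmark_guess <- function(labels) {
  guess <- vapply(emotion_scales(), function(scale) {
    counts <- table(factor(labels[[scale]], levels = emotion_levels()))
    names(counts)[which.max(counts)] # which.max takes the first = lowest level
  }, character(1))
  structure(list(guess = guess), class = "mood_guess_benchmark")
}

#' @export
predict.mood_guess_benchmark <- function(object, newdata, ...) {
  n <- if (is.null(dim(newdata))) {
    if (is.numeric(newdata) && length(newdata) == 1) newdata else 1L
  } else {
    nrow(newdata)
  }
  tibble::as_tibble(lapply(object$guess, function(g) {
    factor(rep(g, n), levels = emotion_levels(), ordered = TRUE)
  }))
}
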