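#' Emotion scales and categories
#'
#' Momentary negative emotion is reported on three visual analog scales
#' (VAS) — depression, anxiety, stress — each an integer slider from 0
#' (usual state) to 100 (most severe). For prediction the continuous range
#' is divided into three ordered categories of equal width: `low`
#' (value < 100/3), `medium` (100/3 <= value < 200/3) and `high`
#' (value >= 200/3). Cut points belong to the upper category.
#'
#' @name emotion-scales
NULL

#' The three emotion scale names
#' @return Character vector `c("depression", "anxiety", "stress")`.
#' @export
emotion_scales <- function() c("depression", "anxiety", "stress")

#' The ordered category levels
#' @return Ordered factor levels `c("low", "medium", "high")`.
#' @export
emotion_levels <- function() c("low", "medium", "high")

#' Map VAS values to three ordered categories
#'
#' @param value Numeric vector of VAS values in `[0, 100]`.
#' @return Ordered factor with levels `low < medium < high`.
#' @examples
#' vas_categorize(c(0, 50, 100))
#' @export
vas_categorize <- function(value) {
  if (any(is.na(value)) || any(value < 0 | value > 100)) {
    abort("VAS values must lie in [0, 100]", class = "moodphone_validation_error")
  }
  cat <- ifelse(value < 100 / 3, "low", ifelse(value < 200 / 3, "medium", "high"))
  factor(cat, levels = emotion_levels(), ordered = TRUE)
}

#' Read an emotion tag file
#'
#' Tag files are CSV with header `timestamp,depression,anxiety,stress`;
#' timestamps are ISO-8601 UTC with seconds, values integers 0-100.
#'
#' @param path File path.
#' @return Tibble with columns `timestamp` (POSIXct UTC), `depression`,
#'   `anxiety`, `stress`.
#' @export
read_emotion_tags <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", rep("numeric", 3)))
  tibble::tibble(
    timestamp = parse_iso(df$timestamp),
    depression = df$depression,
    anxiety = df$anxiety,
    stress = df$stress
  )
}

#' Write an emotion tag file
#'
#' @param tags Tibble with columns `timestamp`, `depression`, `anxiety`,
#'   `stress`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_emotion_tags <- function(tags, path) {
  out <- data.frame(
    timestamp = format_iso(tags$timestamp),
    depression = tags$depression,
    anxiety = tags$anxiety,
    stress = tags$stress
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a user's training tag set
#'
#' A personalized classifier is only trained for users with enough emotion
#' reports; the cutoff defaults to 40 training tags. Tags closer together
#' than `min_gap_hours` raise a warning but are not rejected.
#'
#' @param tags Tibble of emotion tags (see [read_emotion_tags()]).
#' @param minimum Minimum tag count required (default 40).
#' @param min_gap_hours Expected minimum spacing between tags, hours.
#' @return A one-row tibble with columns `n_tags`, `accepted` (logical),
#'   `minimum`.
#' @export
validate_training_set <- function(tags, minimum = 40, min_gap_hours = 3) {
  n <- nrow(tags)
  if (n > 1) {
    ts <- sort(as.numeric(tags$timestamp))
    if (any(diff(ts) < min_gap_hours * 3600 - 1e-6)) {
      warn(sprintf("tags closer together than %g h found", min_gap_hours))
    }
  }
  tibble::tibble(n_tags = n, accepted = n >= minimum, minimum = minimum)
}
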