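#' Windowed usage features
#'
#' For every emotion tag, usage is summarized over the timeslot — the
#' fixed-width window `[tag_time - width, tag_time)` immediately preceding
#' the tag, with candidate widths 0.5, 1, 1.5 and 2 hours. For each usage
#' type (call-in, call-out, missed call, screen usage, each top-ranked app,
#' each app category) four statistics are computed:
#'
#' * `count` — number of events overlapping the window;
#' * `total_duration` — summed in-window duration, seconds (events
#'   straddling the window boundary are clipped to it);
#' * `average_duration` — `total_duration / count`;
#' * `average_interval` — mean of `start_i - end_(i-1)` over consecutive
#'   pairs of contributing events of the same type.
#'
#' Empty windows yield 0 for every statistic, and a single contributing
#' event yields `average_interval = 0` (no pair exists); this keeps the
#' design matrix dense. Feature keys are `"<usage type>|<statistic>"`.
#'
#' @name feature-extraction
NULL

feature_statistics <- c("count", "total_duration", "average_duration", "average_interval")

#' Candidate timeslot widths, in hours
#' @return `c(0.5, 1, 1.5, 2)`.
#' @export
timeslot_widths <- function() c(0.5, 1, 1.5, 2)

#' Default usage types for a user
#'
#' The per-user usage type list is fixed from the training events: the three
#' call event types, screen usage, the user's top-`k` apps by total
#' foreground time, and every app category observed in training.
#'
#' @param events Training-period events tibble.
#' @param k How many top apps to track (default 10).
#' @return Character vector of usage type identifiers; app types are
#'   `"app:<package>"`, categories `"category:<name>"`.
#' @export
usage_types_for_user <- function(events, k = 10) {
  cats <- sort(unique(stats::na.omit(events$category[events$event_type == "app_session"])))
  c(
    "call_in", "call_out", "call_missed", "screen_session",
    paste0("app:", top_apps(events, k)),
    if (length(cats)) paste0("category:", cats)
  )
}

# Subset events matching one usage type identifier; returns numeric
# start/end vectors sorted by start.
events_of_type <- function(events, type) {
  rows <- if (type %in% c("call_in", "call_out", "call_missed", "screen_session")) {
    events$event_type == type
  } else if (startsWith(type, "app:")) {
    events$event_type == "app_session" &
      !is.na(events$package) & events$package == sub("^app:", "", type)
  } else if (startsWith(type, "category:")) {
    events$event_type == "app_session" &
      !is.na(events$category) & events$category == sub("^category:", "", type)
  } else {
    abort(sprintf("unknown usage type: %s", type), class = "moodphone_config_error")
  }
  s <- as.numeric(events$start[rows])
  e <- as.numeric(events$end[rows])
  o <- order(s)
  list(start = s[o], end = e[o])
}

# The four statistics for one pre-subset event list over [t0, t1).
window_stats <- function(ev, t0, t1) {
  hit <- ev$start < t1 & ev$end > t0
  n <- sum(hit)
  if (n == 0) {
    return(c(count = 0, total_duration = 0, average_duration = 0, average_interval = 0))
  }
  cs <- pmax(ev$start[hit], t0)
  ce <- pmin(ev$end[hit], t1)
  tot <- sum(ce - cs)
  iv <- if (n > 1) mean(ev$start[hit][-1] - ev$end[hit][-n]) else 0
  c(
    count = n, total_duration = tot,
    average_duration = tot / n, average_interval = iv
  )
}

#' Extract the feature vector for one tag and timeslot
#'
#' @param events Events tibble (one user).
#' @param at Tag time (POSIXct or seconds).
#' @param width_hours Timeslot width in hours.
#' @param usage_types Character vector of usage type identifiers (see
#'   [usage_types_for_user()]).
#' @return A one-row tibble with one column per feature key
#'   `"<type>|<statistic>"`, in deterministic column order (types in the
#'   given order, statistics count / total_duration / average_duration /
#'   average_interval within each type).
#' @export
extract_features <- function(events, at, width_hours, usage_types) {
  t1 <- as.numeric(at)
  t0 <- t1 - width_hours * 3600
  vals <- unlist(lapply(usage_types, function(ty) {
    window_stats(events_of_type(events, ty), t0, t1)
  }))
  names(vals) <- as.vector(t(outer(usage_types, feature_statistics, paste, sep = "|")))
  tibble::as_tibble(as.list(vals))
}

#' Build the per-user design matrix for one timeslot
#'
#' One row per emotion tag; columns are the windowed usage features in a
#' deterministic, recorded order; three categorical label vectors (one per
#' scale) derived by [vas_categorize()].
#'
#' @param events Training events tibble for one user.
#' @param tags Emotion tag tibble (`timestamp`, `depression`, `anxiety`,
#'   `stress`).
#' @param width_hours Timeslot width in hours.
#' @param usage_types Usage types; derived via [usage_types_for_user()] when
#'   `NULL`.
#' @param top_k Top-app count used when deriving usage types.
#' @return An object of class `mood_design`: a list with `features` (numeric
#'   matrix, tags x feature keys), `labels` (tibble of three ordered
#'   factors), `vas` (tibble of the raw VAS values), `timestamps`,
#'   `width_hours`, `usage_types` and `zero_variance` (flagged constant
#'   columns, retained in the matrix).
#' @export
build_design_matrix <- function(events, tags, width_hours,
                                usage_types = NULL, top_k = 10) {
  if (is.null(usage_types)) {
    usage_types <- usage_types_for_user(events, top_k)
  }
  by_type <- lapply(usage_types, function(ty) events_of_type(events, ty))
  keys <- as.vector(t(outer(usage_types, feature_statistics, paste, sep = "|")))
  t1 <- as.numeric(tags$timestamp)
  X <- matrix(0, nrow = nrow(tags), ncol = length(keys), dimnames = list(NULL, keys))
  for (i in seq_along(t1)) {
    X[i, ] <- unlist(lapply(by_type, window_stats, t1[i] - width_hours * 3600, t1[i]))
  }
  labels <- tibble::tibble(
    depression = vas_categorize(tags$depression),
    anxiety = vas_categorize(tags$anxiety),
    stress = vas_categorize(tags$stress)
  )
  zv <- keys[apply(X, 2, function(v) length(unique(v)) == 1)]
  structure(
    list(
      features = X, labels = labels,
      vas = tags[, c("depression", "anxiety", "stress")],
      timestamps = tags$timestamp, width_hours = width_hours,
      usage_types = usage_types, zero_variance = zv
    ),
    class = "mood_design"
  )
}

#' @export
print.mood_design <- function(x, ...) {
  cat(sprintf(
    "<mood_design> %d tags x %d features, %.1f h timeslot (%d constant columns)\n",
    nrow(x$features), ncol(x$features), x$width_hours, length(x$zero_variance)
  ))
  invisible(x)
}

#' Write a design matrix as CSV plus a JSON sidecar
#'
#' The CSV holds one row per tag (features then the three VAS columns); the
#' sidecar records the column keys, timeslot width and usage types.
#'
#' @param design A `mood_design`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(design, path) {
  df <- data.frame(
    timestamp = format_iso(design$timestamps),
    design$features, check.names = FALSE
  )
  df <- cbind(df, as.data.frame(design$vas))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(
      feature_keys = colnames(design$features),
      width_hours = design$width_hours,
      usage_types = design$usage_types
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
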