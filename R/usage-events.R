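#' Inferring discrete usage events from raw polled samples
#'
#' The logger samples two channels every `sample_period` seconds (3 s by
#' default): the telephony call state (`idle`, `ringing`, `offhook`) and the
#' package name of the app currently occupying the screen. Discrete events
#' are reconstructed from maximal runs of identical samples:
#'
#' * `ringing ... -> idle` becomes a missed call spanning the ringing run;
#' * `ringing ... -> offhook` becomes an incoming call starting at the first
#'   off-hook sample (ringing time is not counted in the call);
#' * `idle -> offhook` with no preceding ringing becomes an outgoing call;
#' * a maximal run of one package name becomes an app session; the union of
#'   app sessions (merged across short gaps) becomes screen usage.
#'
#' Each sample is treated as the left endpoint of a `sample_period`-second
#' occupancy interval, so a run ends at its last sample plus one period and
#' single-sample events have positive duration. A gap longer than
#' `2 * sample_period` between consecutive samples (one dropped poll is
#' tolerated) closes any open run. All intervals are half-open
#' `[start, end)`.
#'
#' @name usage-events
NULL

call_states <- c("idle", "ringing", "offhook")

new_events <- function(event_type = character(), package = character(),
                       start = as.POSIXct(character(), tz = "UTC"),
                       end = as.POSIXct(character(), tz = "UTC")) {
  tibble::tibble(
    event_type = event_type,
    package = package,
    category = rep(NA_character_, length(event_type)),
    start = start,
    end = end,
    duration_s = as.numeric(end) - as.numeric(start)
  )
}

# Split a sample stream into maximal runs of identical `value`, additionally
# broken where consecutive samples are more than 2 * sample_period apart.
# Returns a data.frame of runs with first/last sample times and whether the
# run is contiguous with the next one.
sample_runs <- function(time_s, value, sample_period) {
  n <- length(value)
  if (n == 0) {
    return(NULL)
  }
  brk <- if (n > 1) {
    value[-1] != value[-n] | diff(time_s) > 2 * sample_period
  } else {
    logical(0)
  }
  run_id <- cumsum(c(TRUE, brk))
  first <- tapply(time_s, run_id, function(x) x[1])
  last <- tapply(time_s, run_id, function(x) x[length(x)])
  val <- tapply(value, run_id, function(x) x[1])
  k <- length(val)
  contiguous_next <- c(
    if (k > 1) first[-1] - last[-k] <= 2 * sample_period else logical(0),
    FALSE
  )
  data.frame(
    value = as.character(val),
    first = as.numeric(first),
    last = as.numeric(last),
    contiguous_next = contiguous_next,
    stringsAsFactors = FALSE
  )
}

check_raw_stream <- function(samples, expect_type) {
  if (nrow(samples) == 0) {
    return(invisible(samples))
  }
  if (!all(samples$record_type == expect_type)) {
    abort(sprintf("stream must contain only %s records", expect_type),
      class = "moodphone_validation_error"
    )
  }
  stopifnot_sorted(samples$timestamp, "sample timestamps")
  if (expect_type == "call_state" && !all(samples$value %in% call_states)) {
    bad <- setdiff(unique(samples$value), call_states)
    abort(sprintf("unknown call state token(s): %s", paste(bad, collapse = ", ")),
      class = "moodphone_validation_error"
    )
  }
  invisible(samples)
}

#' Infer call events from a call-state sample stream
#'
#' @param samples Tibble with columns `timestamp` (POSIXct, non-decreasing),
#'   `record_type` (all `"call_state"`), `value` (`idle`/`ringing`/`offhook`).
#' @param sample_period Polling period in seconds (default 3).
#' @return Events tibble with columns `event_type` (`call_in`, `call_out`,
#'   `call_missed`), `package` (`NA`), `category` (`NA`), `start`, `end`
#'   (POSIXct UTC), `duration_s`.
#' @examples
#' s <- tibble::tibble(
#'   timestamp = as.POSIXct("2024-01-01", tz = "UTC") + c(0, 3, 6, 9),
#'   record_type = "call_state",
#'   value = c("idle", "ringing", "ringing", "idle")
#' )
#' infer_call_events(s) # one missed call, 3 s ringing -> 6 s span
#' @export
infer_call_events <- function(samples, sample_period = 3) {
  check_raw_stream(samples, "call_state")
  runs <- sample_runs(as.numeric(samples$timestamp), samples$value, sample_period)
  if (is.null(runs)) {
    return(new_events())
  }
  k <- nrow(runs)
  type <- character(0)
  start <- numeric(0)
  end <- numeric(0)
  for (i in seq_len(k)) {
    st <- runs$value[i]
    if (st == "ringing") {
      answered <- i < k && runs$contiguous_next[i] && runs$value[i + 1] == "offhook"
      if (!answered) {
        type <- c(type, "call_missed")
        start <- c(start, runs$first[i])
        end <- c(end, runs$last[i] + sample_period)
      }
      # answered: the following offhook run emits the call_in
    } else if (st == "offhook") {
      answered <- i > 1 && runs$contiguous_next[i - 1] && runs$value[i - 1] == "ringing"
      type <- c(type, if (answered) "call_in" else "call_out")
      start <- c(start, runs$first[i])
      end <- c(end, runs$last[i] + sample_period)
    }
  }
  new_events(type, rep(NA_character_, length(type)),
    as.POSIXct(start, origin = "1970-01-01", tz = "UTC"),
    as.POSIXct(end, origin = "1970-01-01", tz = "UTC")
  )
}

#' Infer app and screen sessions from a foreground-app sample stream
#'
#' @param samples Tibble with columns `timestamp`, `record_type` (all
#'   `"app"`), `value` (package name on screen).
#' @param sample_period Polling period in seconds (default 3).
#' @return Events tibble containing one `app_session` row per maximal run of
#'   one package, plus `screen_session` rows covering the union of app
#'   sessions (adjacent sessions within `2 * sample_period` merged).
#' @export
infer_app_sessions <- function(samples, sample_period = 3) {
  check_raw_stream(samples, "app")
  runs <- sample_runs(as.numeric(samples$timestamp), samples$value, sample_period)
  if (is.null(runs)) {
    return(new_events())
  }
  app_start <- runs$first
  app_end <- runs$last + sample_period
  # merge app sessions into screen sessions across gaps <= 2 * period
  scr_start <- app_start[1]
  scr_end <- app_end[1]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      m <- length(scr_end)
      if (app_start[i] - scr_end[m] <= 2 * sample_period) {
        scr_end[m] <- max(scr_end[m], app_end[i])
      } else {
        scr_start <- c(scr_start, app_start[i])
        scr_end <- c(scr_end, app_end[i])
      }
    }
  }
  new_events(
    c(rep("app_session", nrow(runs)), rep("screen_session", length(scr_start))),
    c(runs$value, rep(NA_character_, length(scr_start))),
    as.POSIXct(c(app_start, scr_start), origin = "1970-01-01", tz = "UTC"),
    as.POSIXct(c(app_end, scr_end), origin = "1970-01-01", tz = "UTC")
  )
}

#' Rank apps by total foreground time
#'
#' Packages are ranked by total app-session duration over the training
#' period, descending; ties are broken lexicographically by package name.
#'
#' @param events Events tibble (uses `app_session` rows).
#' @param k Number of apps to return (default 10, the "top ten apps").
#' @return Character vector of up to `k` package names.
#' @export
top_apps <- function(events, k = 10) {
  apps <- dplyr::filter(events, .data$event_type == "app_session")
  if (nrow(apps) == 0) {
    return(character(0))
  }
  tot <- apps %>%
    dplyr::group_by(.data$package) %>%
    dplyr::summarise(total = sum(.data$duration_s), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$total), .data$package)
  utils::head(tot$package, k)
}

#' Annotate app sessions with an app category
#'
#' @param events Events tibble.
#' @param mapping Named character vector (`package -> category`) or a data
#'   frame with columns `package` and `category`. Unmapped packages get
#'   category `"other"`.
#' @return `events` with the `category` column filled for `app_session`
#'   rows.
#' @export
categorize_apps <- function(events, mapping = character()) {
  if (is.data.frame(mapping)) {
    mapping <- stats::setNames(as.character(mapping$category), mapping$package)
  }
  is_app <- events$event_type == "app_session"
  cat <- unname(mapping[events$package[is_app]])
  cat[is.na(cat)] <- "other"
  events$category[is_app] <- cat
  events
}

#' Infer all usage events from a raw log
#'
#' Convenience wrapper: splits a mixed raw log into its call-state and app
#' channels, infers call events, app sessions and screen sessions, annotates
#' app categories, and returns everything sorted by start time.
#'
#' @param raw Raw log tibble (`timestamp`, `record_type`, `value`).
#' @param mapping Package-to-category mapping (see [categorize_apps()]).
#' @param sample_period Polling period in seconds.
#' @return Events tibble sorted by `start`, then `event_type`.
#' @export
infer_usage_events <- function(raw, mapping = character(), sample_period = 3) {
  calls <- infer_call_events(
    dplyr::filter(raw, .data$record_type == "call_state"), sample_period
  )
  apps <- infer_app_sessions(
    dplyr::filter(raw, .data$record_type == "app"), sample_period
  )
  dplyr::bind_rows(calls, categorize_apps(apps, mapping)) %>%
    dplyr::arrange(.data$start, .data$event_type)
}
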