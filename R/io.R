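#' Raw log and fixture files
#'
#' All files are plain CSV with a header and ISO-8601 UTC timestamps with
#' seconds. The raw log schema is `timestamp,record_type,value` with
#' `record_type` one of `call_state` / `app`; emotion tag files are
#' `timestamp,depression,anxiety,stress` (integers 0-100); ground truth is
#' a JSON file of the planted per-scale weights.
#'
#' @name fixture-files
NULL

#' Read a raw usage log
#' @param path CSV path.
#' @return Tibble `timestamp` (POSIXct UTC), `record_type`, `value`.
#' @export
read_raw_log <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  tibble::tibble(
    timestamp = parse_iso(df$timestamp),
    record_type = df$record_type,
    value = df$value
  )
}

#' Write a raw usage log
#' @param raw Tibble `timestamp`, `record_type`, `value`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_raw_log <- function(raw, path) {
  utils::write.csv(
    data.frame(
      timestamp = format_iso(raw$timestamp),
      record_type = raw$record_type,
      value = raw$value
    ),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write inferred events
#' @param events Events tibble.
#' @param user_id User identifier written into each row.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, user_id, path) {
  utils::write.csv(
    data.frame(
      user_id = user_id,
      event_type = events$event_type,
      package_or_empty = ifelse(is.na(events$package), "", events$package),
      category = ifelse(is.na(events$category), "", events$category),
      start_iso = format_iso(events$start),
      end_iso = format_iso(events$end),
      duration_s = events$duration_s
    ),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write one simulated user's fixture files
#'
#' Writes `raw_log.csv`, `tags_train.csv`, `tags_eval.csv` (responded
#' predictions only) and `ground_truth.json` under `dir`. The files
#' round-trip losslessly through [read_raw_log()] and
#' [read_emotion_tags()].
#'
#' @param sim A `mood_sim_user` from [simulate_user()] (needs `raw`).
#' @param dir Output directory (created if missing).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    abort(sprintf("cannot create fixture directory: %s", dir),
      class = "moodphone_io_error"
    )
  }
  if (is.null(sim$raw)) {
    abort("simulate_user() was run with raw = FALSE; no raw stream to write",
      class = "moodphone_io_error"
    )
  }
  paths <- c(
    raw_log = file.path(dir, "raw_log.csv"),
    tags_train = file.path(dir, "tags_train.csv"),
    tags_eval = file.path(dir, "tags_eval.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_raw_log(sim$raw, paths[["raw_log"]])
  train <- dplyr::filter(sim$tags, .data$phase == "train")
  evalr <- dplyr::filter(sim$tags, .data$phase == "eval", .data$responded)
  write_emotion_tags(train, paths[["tags_train"]])
  write_emotion_tags(evalr, paths[["tags_eval"]])
  jsonlite::write_json(
    list(
      user_id = sim$user_id,
      baseline = sim$truth$baseline,
      window_hours = sim$truth$window_hours,
      effect_size = sim$truth$effect_size,
      noise_sd = sim$truth$noise_sd,
      eval_start = format_iso(sim$eval_start),
      weights = sim$truth$weights,
      feature_stats = sim$truth$feature_stats
    ),
    paths[["ground_truth"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Read a ground-truth file
#' @param path JSON path written by [write_fixture()].
#' @return List with the planted weights and scaling constants.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$weights <- tibble::as_tibble(gt$weights)
  gt$feature_stats <- tibble::as_tibble(gt$feature_stats)
  gt$eval_start <- parse_iso(gt$eval_start)
  gt
}
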