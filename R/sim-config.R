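#' Default app catalog
#'
#' A small catalog of package names and categories used by the synthetic
#' generator; real deployments supply their own package-to-category
#' mapping.
#'
#' @return Tibble with columns `package` and `category`.
#' @export
default_app_catalog <- function() {
  tibble::tibble(
    package = c(
      "com.chat.blue", "com.mail.box",
      "com.social.feed", "com.social.pics",
      "com.video.stream", "com.game.puzzle",
      "com.docs.edit", "com.cal.plan"
    ),
    category = c(
      "communication", "communication",
      "social", "social",
      "entertainment", "entertainment",
      "productivity", "productivity"
    )
  )
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic cohort: 14
#' training days with 4 emotion tags per day at least 3 hours apart, a
#' 5-day evaluation phase, and usage channels polled every 3 seconds.
#' `effect_size` is the strength of the planted usage-to-emotion coupling
#' in VAS points per standard deviation of the combined planted signal
#' (0 = emotions independent of usage); `noise_sd` is the VAS noise
#' standard deviation.
#'
#' @param n_users Number of users to simulate.
#' @param n_days_train Training days (default 14).
#' @param n_days_eval Evaluation days (default 5).
#' @param tags_per_day Emotion tags per training day (default 4).
#' @param min_tag_gap Minimum hours between tags (default 3).
#' @param sample_period Polling period in seconds (default 3).
#' @param effect_size Usage-to-emotion coupling, VAS points (default 20).
#' @param noise_sd VAS noise standard deviation, points (default 10).
#' @param respond_prob Probability a user responds to an evaluation-phase
#'   prediction (default 0.987).
#' @param seed Master seed; per-user streams are derived sub-streams.
#' @param app_catalog Tibble `package`/`category` (default
#'   [default_app_catalog()]).
#' @param planted Feature keys carrying the planted dependence, computed
#'   over the 2-hour window preceding each tag.
#' @param start_date First day of the training phase (UTC).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_users = 10, n_days_train = 14, n_days_eval = 5,
                       tags_per_day = 4, min_tag_gap = 3, sample_period = 3,
                       effect_size = 20, noise_sd = 10, respond_prob = 0.987,
                       seed = 1L, app_catalog = default_app_catalog(),
                       planted = c(
                         "screen_session|total_duration",
                         "call_out|count",
                         "category:social|total_duration"
                       ),
                       start_date = "2024-03-04") {
  cfg <- list(
    n_users = n_users, n_days_train = n_days_train, n_days_eval = n_days_eval,
    tags_per_day = tags_per_day, min_tag_gap = min_tag_gap,
    sample_period = sample_period, effect_size = effect_size,
    noise_sd = noise_sd, respond_prob = respond_prob, seed = as.integer(seed),
    app_catalog = app_catalog, planted = planted, start_date = start_date
  )
  bad <- function(field, why) {
    abort(sprintf("invalid sim_config field '%s': %s", field, why),
      class = "moodphone_config_error"
    )
  }
  if (!is.numeric(n_users) || n_users < 1) bad("n_users", "must be >= 1")
  if (!is.numeric(n_days_train) || n_days_train < 1) bad("n_days_train", "must be >= 1")
  if (!is.numeric(n_days_eval) || n_days_eval < 0) bad("n_days_eval", "must be >= 0")
  if (!is.numeric(tags_per_day) || tags_per_day < 1) bad("tags_per_day", "must be >= 1")
  if (tags_per_day * min_tag_gap > 24) {
    bad("min_tag_gap", "tags_per_day * min_tag_gap must be <= 24 h")
  }
  if (!is.numeric(sample_period) || sample_period <= 0) {
    bad("sample_period", "must be > 0")
  }
  if (!is.numeric(effect_size) || effect_size < 0) bad("effect_size", "must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd <= 0) bad("noise_sd", "must be > 0")
  if (!is.numeric(respond_prob) || respond_prob < 0 || respond_prob > 1) {
    bad("respond_prob", "must be in [0, 1]")
  }
  if (!is.data.frame(app_catalog) ||
    !all(c("package", "category") %in% names(app_catalog))) {
    bad("app_catalog", "needs columns package and category")
  }
  ok_stat <- vapply(strsplit(planted, "|", fixed = TRUE), function(p) {
    length(p) == 2 && p[2] %in% feature_statistics
  }, logical(1))
  if (!all(ok_stat)) bad("planted", "keys must be '<usage type>|<statistic>'")
  structure(cfg, class = "sim_config")
}
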