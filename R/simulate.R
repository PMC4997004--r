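#' Synthetic user simulation
#'
#' Generates, per user, a raw usage log (call-state and foreground-app
#' samples), emotion tags for the training phase, evaluation-phase
#' responses on the 7-per-day prediction schedule, and the ground truth of
#' the planted usage-to-emotion dependence.
#'
#' Usage streams are marked point processes over a 08:00-24:00 waking
#' window: calls arrive as a Poisson process with per-user incoming and
#' outgoing rates (incoming calls ring first and are answered with a
#' per-user probability; unanswered ringing becomes a missed call), app
#' sessions follow a renewal process with a per-user categorical app
#' preference, and call/session durations are log-normal. All event times
#' are quantized to the polling grid and episodes are separated by more
#' than twice the polling period, so event inference from the emitted
#' samples reconstructs the generated events exactly.
#'
#' Each tag's three VAS values are a linear function of the planted
#' features computed over the 2-hour window preceding the tag
#' (standardized per user), scaled so that `effect_size` is the standard
#' deviation of the systematic component in VAS points, plus Gaussian
#' noise, rounded and clipped to 0-100.
#'
#' @param config A [sim_config()].
#' @param user_id User identifier string.
#' @param raw Also expand events into the polled raw sample stream
#'   (default `TRUE`; disable for large Monte-Carlo runs that consume
#'   events directly).
#' @return List of class `mood_sim_user` with elements `user_id`, `events`
#'   (true generated events), `raw` (sample stream or `NULL`), `tags`
#'   (train + eval rows with `phase` and `responded` columns), `truth`
#'   (planted weights, standardization constants, per-tag latents) and
#'   `eval_start` (POSIXct boundary between phases).
#' @export
simulate_user <- function(config, user_id, raw = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, paste0("user:", user_id)), {
    sim_user_impl(config, user_id, raw)
  })
}

sim_user_impl <- function(config, user_id, raw) {
  per <- config$sample_period
  t0 <- as.numeric(as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC"))
  n_days <- config$n_days_train + config$n_days_eval
  eval_start <- t0 + config$n_days_train * 86400
  q <- function(x) t0 + round((x - t0) / per) * per

  # per-user behavioral parameters
  rate_in <- stats::rlnorm(1, log(0.25), 0.4) # incoming calls / waking hour
  rate_out <- stats::rlnorm(1, log(0.30), 0.4)
  p_answer <- stats::runif(1, 0.6, 0.9)
  rate_sess <- stats::rlnorm(1, log(2), 0.3) # app sessions / waking hour
  mu_sess <- log(150) + stats::rnorm(1, 0, 0.3)
  mu_call <- log(90) + stats::rnorm(1, 0, 0.3)
  prefs <- stats::rgamma(nrow(config$app_catalog), 1.2)
  prefs <- prefs / sum(prefs)

  # --- call episodes -------------------------------------------------------
  episodes <- list()
  for (d in seq_len(n_days)) {
    wake <- t0 + (d - 1) * 86400 + 8 * 3600
    n_in <- stats::rpois(1, rate_in * 16)
    n_out <- stats::rpois(1, rate_out * 16)
    starts <- sort(stats::runif(n_in + n_out, wake, wake + 16 * 3600))
    incoming <- sample(rep(c(TRUE, FALSE), c(n_in, n_out)))
    for (i in seq_along(starts)) {
      s <- q(starts[i])
      if (incoming[i]) {
        ring <- per * sample(2:10, 1)
        if (stats::runif(1) < p_answer) {
          dur <- max(per, q(t0 + stats::rlnorm(1, mu_call, 0.9)) - t0)
          episodes[[length(episodes) + 1]] <- list(
            type = "call_in", ring_start = s, off_start = s + ring,
            off_end = s + ring + dur
          )
        } else {
          episodes[[length(episodes) + 1]] <- list(
            type = "call_missed", ring_start = s, off_start = NA,
            off_end = s + ring
          )
        }
      } else {
        dur <- max(per, q(t0 + stats::rlnorm(1, mu_call, 0.9)) - t0)
        episodes[[length(episodes) + 1]] <- list(
          type = "call_out", ring_start = NA, off_start = s, off_end = s + dur
        )
      }
    }
  }
  # one phone: drop episodes overlapping (or polled-adjacent to) the previous
  kept <- list()
  last_end <- -Inf
  for (ep in episodes) {
    ep_start <- if (is.na(ep$ring_start)) ep$off_start else ep$ring_start
    if (ep_start > last_end + 2 * per) {
      kept[[length(kept) + 1]] <- ep
      last_end <- ep$off_end
    }
  }
  episodes <- kept
  call_events <- if (length(episodes)) {
    tibble::tibble(
      event_type = vapply(episodes, `[[`, character(1), "type"),
      package = NA_character_, category = NA_character_,
      start = vapply(episodes, function(e) {
        if (e$type == "call_missed") e$ring_start else e$off_start
      }, numeric(1)),
      end = vapply(episodes, `[[`, numeric(1), "off_end")
    )
  } else {
    tibble::tibble(
      event_type = character(), package = character(), category = character(),
      start = numeric(), end = numeric()
    )
  }

  # --- app sessions --------------------------------------------------------
  sess_start <- numeric()
  sess_end <- numeric()
  sess_app <- character()
  mean_gap <- max(60, 3600 / rate_sess - exp(mu_sess + 0.9^2 / 2))
  for (d in seq_len(n_days)) {
    wake <- t0 + (d - 1) * 86400 + 8 * 3600
    day_end <- wake + 16 * 3600
    t <- wake + stats::rexp(1, 1 / mean_gap)
    while (t < day_end) {
      dur <- max(per, q(t0 + stats::rlnorm(1, mu_sess, 0.9)) - t0)
      s <- q(t)
      e <- min(s + dur, q(day_end))
      if (e > s) {
        sess_start <- c(sess_start, s)
        sess_end <- c(sess_end, e)
        sess_app <- c(sess_app, sample(config$app_catalog$package, 1, prob = prefs))
      }
      t <- e + 3 * per + stats::rexp(1, 1 / mean_gap)
    }
  }
  app_events <- tibble::tibble(
    event_type = rep("app_session", length(sess_start)),
    package = sess_app, category = NA_character_,
    start = sess_start, end = sess_end
  )
  # screen sessions: union of app sessions merged across gaps <= 2 * period
  scr <- if (nrow(app_events)) {
    ss <- sess_start
    se <- sess_end
    ms <- ss[1]
    me <- se[1]
    if (length(ss) > 1) {
      for (i in 2:length(ss)) {
        k <- length(me)
        if (ss[i] - me[k] <= 2 * per) {
          me[k] <- max(me[k], se[i])
        } else {
          ms <- c(ms, ss[i])
          me <- c(me, se[i])
        }
      }
    }
    tibble::tibble(
      event_type = rep("screen_session", length(ms)),
      package = NA_character_, category = NA_character_, start = ms, end = me
    )
  } else {
    app_events[0, ]
  }

  mapping <- stats::setNames(config$app_catalog$category, config$app_catalog$package)
  events <- dplyr::bind_rows(call_events, app_events, scr) %>%
    dplyr::mutate(
      category = ifelse(.data$event_type == "app_session",
        unname(mapping[.data$package]), NA_character_
      ),
      duration_s = .data$end - .data$start
    ) %>%
    dplyr::arrange(.data$start, .data$event_type) %>%
    dplyr::mutate(
      start = as.POSIXct(.data$start, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(.data$end, origin = "1970-01-01", tz = "UTC")
    )

  # --- tag times -----------------------------------------------------------
  k <- config$tags_per_day
  spacing <- if (k > 1) max(config$min_tag_gap, 14 / (k - 1)) else 0
  jitter_amp <- if (k > 1) min(0.5, (spacing - config$min_tag_gap) / 2) else 3
  train_times <- numeric()
  for (d in seq_len(config$n_days_train)) {
    day0 <- t0 + (d - 1) * 86400
    anchors <- 8 + (seq_len(k) - 1) * spacing + 1 # hours, first ~09:00
    jit <- stats::runif(k, -jitter_amp, jitter_amp)
    train_times <- c(train_times, round(day0 + (anchors + jit) * 3600))
  }
  eval_times <- numeric()
  if (config$n_days_eval > 0) {
    for (d in seq_len(config$n_days_eval)) {
      day0 <- eval_start + (d - 1) * 86400
      eval_times <- c(eval_times, day0 + 3600 * seq(11, 23, by = 2))
    }
  }
  responded <- if (length(eval_times)) {
    stats::runif(length(eval_times)) < config$respond_prob
  } else {
    logical(0)
  }

  # --- VAS values from planted features ------------------------------------
  all_times <- c(train_times, eval_times)
  Z <- vapply(config$planted, function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    ev <- events_of_type(events, parts[1])
    vapply(all_times, function(tt) {
      window_stats(ev, tt - 2 * 3600, tt)[[parts[2]]]
    }, numeric(1))
  }, numeric(length(all_times)))
  Z <- matrix(Z, nrow = length(all_times))
  f_mean <- colMeans(Z)
  f_sd <- apply(Z, 2, stats::sd)
  f_sd[f_sd == 0 | is.na(f_sd)] <- 1
  Zs <- sweep(sweep(Z, 2, f_mean), 2, f_sd, "/")

  weights <- list()
  vas <- matrix(NA_real_, length(all_times), 3,
    dimnames = list(NULL, emotion_scales())
  )
  latent <- vas
  for (scale in emotion_scales()) {
    w <- sample(c(-1, 1), length(config$planted), replace = TRUE) *
      stats::runif(length(config$planted), 0.6, 1)
    signal <- as.numeric(Zs %*% w)
    s_sd <- stats::sd(signal)
    if (is.na(s_sd) || s_sd == 0) s_sd <- 1
    lat <- 50 + config$effect_size * signal / s_sd
    latent[, scale] <- lat
    vas[, scale] <- pmin(pmax(round(lat + stats::rnorm(length(lat), 0, config$noise_sd)), 0), 100)
    weights[[scale]] <- tibble::tibble(
      scale = scale, feature = config$planted,
      weight = if (config$effect_size > 0) config$effect_size * w / s_sd else 0
    )
  }

  tags <- tibble::tibble(
    timestamp = as.POSIXct(all_times, origin = "1970-01-01", tz = "UTC"),
    depression = vas[, "depression"],
    anxiety = vas[, "anxiety"],
    stress = vas[, "stress"],
    phase = rep(c("train", "eval"), c(length(train_times), length(eval_times))),
    responded = c(rep(TRUE, length(train_times)), responded)
  )

  truth <- list(
    user_id = user_id,
    weights = dplyr::bind_rows(weights),
    baseline = 50, window_hours = 2,
    effect_size = config$effect_size, noise_sd = config$noise_sd,
    feature_stats = tibble::tibble(
      feature = config$planted, mean = f_mean, sd = f_sd
    ),
    latent = tibble::tibble(
      timestamp = tags$timestamp, phase = tags$phase,
      depression = latent[, "depression"],
      anxiety = latent[, "anxiety"],
      stress = latent[, "stress"]
    )
  )

  structure(
    list(
      user_id = user_id,
      events = events,
      raw = if (raw) expand_raw_samples(episodes, app_events, per) else NULL,
      tags = tags,
      truth = truth,
      eval_start = as.POSIXct(eval_start, origin = "1970-01-01", tz = "UTC")
    ),
    class = "mood_sim_user"
  )
}

# Expand generated episodes/sessions into the polled raw sample stream.
# Samples are the left endpoints of `per`-second occupancy intervals; call
# episodes are bracketed by idle samples so state transitions are explicit.
expand_raw_samples <- function(episodes, app_events, per) {
  ct <- numeric()
  cv <- character()
  for (ep in episodes) {
    if (ep$type == "call_missed") {
      rs <- seq(ep$ring_start, ep$off_end - per, by = per)
      ct <- c(ct, ep$ring_start - per, rs, ep$off_end)
      cv <- c(cv, "idle", rep("ringing", length(rs)), "idle")
    } else if (ep$type == "call_in") {
      rs <- seq(ep$ring_start, ep$off_start - per, by = per)
      os <- seq(ep$off_start, ep$off_end - per, by = per)
      ct <- c(ct, ep$ring_start - per, rs, os, ep$off_end)
      cv <- c(cv, "idle", rep("ringing", length(rs)), rep("offhook", length(os)), "idle")
    } else {
      os <- seq(ep$off_start, ep$off_end - per, by = per)
      ct <- c(ct, ep$off_start - per, os, ep$off_end)
      cv <- c(cv, "idle", rep("offhook", length(os)), "idle")
    }
  }
  at <- numeric()
  av <- character()
  if (nrow(app_events)) {
    for (i in seq_len(nrow(app_events))) {
      s <- seq(app_events$start[i], app_events$end[i] - per, by = per)
      at <- c(at, s)
      av <- c(av, rep(app_events$package[i], length(s)))
    }
  }
  raw <- tibble::tibble(
    timestamp = c(ct, at),
    record_type = rep(c("call_state", "app"), c(length(ct), length(at))),
    value = c(cv, av)
  ) %>%
    dplyr::arrange(.data$timestamp, .data$record_type) %>%
    dplyr::mutate(
      timestamp = as.POSIXct(.data$timestamp, origin = "1970-01-01", tz = "UTC")
    )
  raw
}

#' Simulate a cohort of users
#'
#' @param config A [sim_config()].
#' @param raw Expand raw sample streams (see [simulate_user()]).
#' @return Named list of `mood_sim_user` objects (`u01`, `u02`, ...).
#' @export
simulate_cohort <- function(config, raw = TRUE) {
  ids <- sprintf("u%02d", seq_len(config$n_users))
  stats::setNames(lapply(ids, function(id) simulate_user(config, id, raw)), ids)
}
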