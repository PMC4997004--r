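# Builders and independent brute-force oracles used across test files.

t_origin <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")

# A sample stream from offsets (seconds) and values.
make_stream <- function(offsets, values, record_type) {
  tibble::tibble(
    timestamp = t_origin + offsets,
    record_type = record_type,
    value = values
  )
}

call_stream <- function(offsets, states) make_stream(offsets, states, "call_state")
app_stream <- function(offsets, pkgs) make_stream(offsets, pkgs, "app")

# Exact second offsets (avoids difftime's auto-unit float round trip).
to_secs <- function(t) as.numeric(t) - as.numeric(t_origin)

# An events tibble from plain vectors of second offsets.
make_events <- function(event_type, start_s, end_s, package = NA_character_,
                        category = NA_character_) {
  tibble::tibble(
    event_type = event_type,
    package = rep_len(package, length(event_type)),
    category = rep_len(category, length(event_type)),
    start = t_origin + start_s,
    end = t_origin + end_s,
    duration_s = end_s - start_s
  )
}

# ---- per-second oracles ----------------------------------------------------
# Independent reconstruction used to validate run-length event inference:
# each sample occupies [t, t + period) seconds; when the next sample has the
# SAME value and arrives within 2 * period (one dropped poll), the state is
# carried forward to it. Maximal same-value covered segments are then read
# off the per-second array; two segments count as adjacent (a transition)
# when the uncovered gap between them is at most one period, which is
# exactly the span a tolerated dropped poll can leave between two
# different-valued samples.

expand_state_per_second <- function(offsets, values, period) {
  n <- length(offsets)
  end <- offsets[n] + period
  state <- rep(NA_character_, end - offsets[1])
  for (i in seq_len(n)) {
    upto <- if (i < n && values[i + 1] == values[i] &&
      offsets[i + 1] - offsets[i] <= 2 * period) {
      offsets[i + 1]
    } else {
      offsets[i] + period
    }
    span <- seq(offsets[i], min(upto, end) - 1)
    state[span - offsets[1] + 1] <- values[i]
  }
  list(t0 = offsets[1], state = state)
}

# Covered (non-gap) segments with an `adjacent_prev` flag.
state_segments <- function(exp, period) {
  st <- exp$state
  st[is.na(st)] <- ".gap"
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  seg <- data.frame(
    value = r$values,
    start = exp$t0 + starts - 1,
    end = exp$t0 + ends
  )
  seg <- seg[seg$value != ".gap", , drop = FALSE]
  seg$adjacent_prev <- c(
    FALSE,
    if (nrow(seg) > 1) seg$start[-1] - seg$end[-nrow(seg)] <= period else logical(0)
  )
  seg
}

oracle_call_events <- function(offsets, states, period) {
  if (length(offsets) == 0) {
    return(make_events(character(), numeric(), numeric()))
  }
  seg <- state_segments(expand_state_per_second(offsets, states, period), period)
  out <- list()
  for (i in seq_len(nrow(seg))) {
    v <- seg$value[i]
    if (v == "ringing") {
      answered <- i < nrow(seg) && seg$adjacent_prev[i + 1] &&
        seg$value[i + 1] == "offhook"
      if (!answered) {
        out[[length(out) + 1]] <- c("call_missed", seg$start[i], seg$end[i])
      }
    } else if (v == "offhook") {
      answered <- i > 1 && seg$adjacent_prev[i] && seg$value[i - 1] == "ringing"
      out[[length(out) + 1]] <- c(
        if (answered) "call_in" else "call_out", seg$start[i], seg$end[i]
      )
    }
  }
  if (!length(out)) {
    return(make_events(character(), numeric(), numeric()))
  }
  m <- do.call(rbind, out)
  make_events(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]))
}

oracle_app_sessions <- function(offsets, pkgs, period) {
  if (length(offsets) == 0) {
    return(make_events(character(), numeric(), numeric()))
  }
  seg <- state_segments(expand_state_per_second(offsets, pkgs, period), period)
  make_events(rep("app_session", nrow(seg)), seg$start, seg$end,
    package = seg$value
  )
}

# Per-second accumulation of in-window duration for one set of intervals.
oracle_total_duration <- function(start_s, end_s, w0, w1) {
  if (length(start_s) == 0 || w1 <= w0) {
    return(0)
  }
  secs <- seq(w0, w1 - 1)
  covered <- rep(FALSE, length(secs))
  for (i in seq_along(start_s)) {
    covered <- covered | (secs >= start_s[i] & secs < end_s[i])
  }
  sum(covered)
}

# Random legal call-state stream on the 3-s grid (for oracle equivalence).
random_call_stream <- function(n, seed, period = 3) {
  withr::with_seed(seed, {
    offs <- cumsum(sample(c(period, period, period, 2 * period, 5 * period),
      n,
      replace = TRUE
    ))
    state <- character(n)
    cur <- "idle"
    for (i in seq_len(n)) {
      gap_broke <- i > 1 && offs[i] - offs[i - 1] > 2 * period
      if (gap_broke) cur <- sample(c("idle", "ringing", "offhook"), 1)
      cur <- switch(cur,
        idle = sample(c("idle", "idle", "ringing", "offhook"), 1),
        ringing = sample(c("ringing", "idle", "offhook"), 1),
        offhook = sample(c("offhook", "offhook", "idle"), 1)
      )
      state[i] <- cur
    }
    call_stream(offs, state)
  })
}

random_app_stream <- function(n, seed, period = 3) {
  withr::with_seed(seed, {
    offs <- cumsum(sample(c(period, period, 2 * period, 4 * period),
      n,
      replace = TRUE
    ))
    app_stream(offs, sample(c("app.a", "app.b", "app.c"), n,
      replace = TRUE, prob = c(0.5, 0.3, 0.2)
    ))
  })
}

# Small labelled feature matrix with one informative column.
planted_matrix <- function(n = 60, p = 6, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    y <- factor(rep(c("low", "medium", "high"), length.out = n),
      levels = c("low", "medium", "high"), ordered = TRUE
    )
    X <- matrix(rnorm(n * p), n, p,
      dimnames = list(NULL, paste0("feat", seq_len(p)))
    )
    X[, 1] <- X[, 1] + sep * (as.integer(y) - 2)
    list(X = X, y = y)
  })
}

fast_sim_config <- function(...) {
  sim_config(
    app_catalog = default_app_catalog()[1:6, ],
    ...
  )
}

# Split one simulated user into training/eval pieces for the in-memory
# pipeline functions.
sim_train_user <- function(sim) {
  list(
    events = dplyr::filter(sim$events, start < sim$eval_start),
    tags = dplyr::filter(sim$tags, phase == "train")
  )
}

sim_eval_user <- function(sim, n_days_eval) {
  resp <- dplyr::filter(sim$tags, phase == "eval", responded)
  list(
    events = sim$events,
    responses = resp,
    days = as.Date(sim$eval_start) + seq_len(n_days_eval) - 1
  )
}
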