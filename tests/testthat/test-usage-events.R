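test_that("call transitions produce the expected events", {
  # ringing run ending in idle: one missed call spanning the ringing run
  missed <- infer_call_events(call_stream(c(0, 3, 6, 9), c("idle", "ringing", "ringing", "idle")))
  expect_equal(nrow(missed), 1)
  expect_equal(missed$event_type, "call_missed")
  expect_equal(to_secs(missed$start), 3)
  expect_equal(missed$duration_s, 6)

  # idle -> offhook with no ringing: outgoing call, 6 s
  out <- infer_call_events(call_stream(c(0, 3, 6, 9), c("idle", "offhook", "offhook", "idle")))
  expect_equal(out$event_type, "call_out")
  expect_equal(out$duration_s, 6)

  # ringing answered: call_in starts at the first offhook sample
  cin <- infer_call_events(call_stream(
    c(0, 3, 6, 9, 12, 15),
    c("idle", "ringing", "ringing", "offhook", "offhook", "idle")
  ))
  expect_equal(cin$event_type, "call_in")
  expect_equal(to_secs(cin$start), 9)
  expect_equal(cin$duration_s, 6)

  expect_equal(nrow(infer_call_events(call_stream(numeric(), character()))), 0)
})

test_that("a long gap closes an open call run", {
  ev <- infer_call_events(call_stream(
    c(0, 3, 300, 303),
    c("offhook", "offhook", "idle", "idle")
  ))
  expect_equal(ev$event_type, "call_out")
  expect_equal(ev$duration_s, 6) # closed at last offhook sample + period
})

test_that("invalid call streams are rejected", {
  expect_error(
    infer_call_events(call_stream(c(3, 0), c("idle", "idle"))),
    class = "moodphone_validation_error"
  )
  expect_error(
    infer_call_events(call_stream(0, "dialing")),
    class = "moodphone_validation_error"
  )
})

test_that("app runs become sessions with the closing-sample convention", {
  ev <- infer_app_sessions(app_stream(c(0, 3, 6, 9), c("A", "A", "B", "B")))
  apps <- ev[ev$event_type == "app_session", ]
  expect_equal(apps$package, c("A", "B"))
  expect_equal(to_secs(apps$start), c(0, 6))
  expect_equal(to_secs(apps$end), c(6, 12))
  # adjacent sessions merge into one screen session
  scr <- ev[ev$event_type == "screen_session", ]
  expect_equal(nrow(scr), 1)
  expect_equal(scr$duration_s, 12)

  single <- infer_app_sessions(app_stream(0, "A"))
  expect_equal(single$duration_s[single$event_type == "app_session"], 3)

  gap <- infer_app_sessions(app_stream(c(0, 300), c("A", "A")))
  expect_equal(sum(gap$event_type == "app_session"), 2)
  expect_equal(sum(gap$event_type == "screen_session"), 2)
})

test_that("top apps rank by total duration with lexicographic ties", {
  ev <- make_events(
    rep("app_session", 4), c(0, 200, 500, 800), c(100, 400, 600, 900),
    package = c("b.app", "a.app", "c.app", "a.app")
  )
  # a.app 300 s, b.app 100 s, c.app 100 s
  expect_equal(top_apps(ev, 2), c("a.app", "b.app"))
  expect_equal(top_apps(ev, 10), c("a.app", "b.app", "c.app"))
  expect_equal(top_apps(make_events(character(), numeric(), numeric()), 3), character(0))
})

test_that("app categorization falls back to 'other'", {
  ev <- make_events(c("app_session", "app_session"), c(0, 10), c(5, 15),
    package = c("a.app", "b.app")
  )
  got <- categorize_apps(ev, c(a.app = "social"))
  expect_equal(got$category, c("social", "other"))
  expect_equal(categorize_apps(ev, character())$category, c("other", "other"))
  expect_equal(
    categorize_apps(ev, tibble::tibble(package = "b.app", category = "games"))$category,
    c("other", "games")
  )
})

test_that("events files carry the documented columns", {
  ev <- make_events(c("call_in", "app_session"), c(0, 50), c(30, 80),
    package = c(NA, "a.app"), category = c(NA, "social")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, "u01", path)
  back <- utils::read.csv(path)
  expect_equal(
    names(back),
    c(
      "user_id", "event_type", "package_or_empty", "category",
      "start_iso", "end_iso", "duration_s"
    )
  )
  expect_equal(back$package_or_empty, c("", "a.app"))
  expect_equal(back$duration_s, c(30, 30))
})

test_that("the command-line wrapper parses cleanly", {
  cli <- system.file("cli", "moodphone.R", package = "moodphone")
  expect_true(file.exists(cli))
  expect_silent(parse(file = cli))
})

test_that("interleaving the two channels does not change inference", {
  calls <- call_stream(c(0, 3, 6, 9), c("idle", "ringing", "ringing", "idle"))
  apps <- app_stream(c(1, 4, 7), c("A", "A", "B"))
  mixed1 <- dplyr::arrange(dplyr::bind_rows(calls, apps), timestamp)
  mixed2 <- dplyr::bind_rows(apps, calls) # unsorted interleaving, per-type order kept
  expect_equal(
    infer_usage_events(mixed1, c(A = "x")),
    infer_usage_events(mixed2, c(A = "x"))
  )
})

test_that("event inference matches per-second brute-force reconstruction", {
  for (seed in 1:25) {
    cs <- random_call_stream(60, seed)
    got <- infer_call_events(cs)
    want <- oracle_call_events(
      to_secs(cs$timestamp), cs$value, 3
    )
    expect_equal(got[, c("event_type", "start", "end")],
      want[, c("event_type", "start", "end")],
      info = paste("call seed", seed)
    )
    as <- random_app_stream(60, seed + 1000)
    got_a <- infer_app_sessions(as)
    got_a <- got_a[got_a$event_type == "app_session", ]
    want_a <- oracle_app_sessions(
      to_secs(as$timestamp), as$value, 3
    )
    expect_equal(got_a[, c("package", "start", "end")],
      want_a[, c("package", "start", "end")],
      info = paste("app seed", seed)
    )
  }
})

test_that("screen usage bounds the app sessions", {
  for (seed in 1:5) {
    as <- random_app_stream(80, seed)
    ev <- infer_app_sessions(as)
    apps <- ev[ev$event_type == "app_session", ]
    scr <- ev[ev$event_type == "screen_session", ]
    expect_gte(sum(scr$duration_s), max(apps$duration_s))
    # merging may bridge up to 2 x period between adjacent sessions
    expect_lte(
      sum(scr$duration_s),
      sum(apps$duration_s) + 2 * 3 * max(nrow(apps) - 1, 0)
    )
  }
})
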