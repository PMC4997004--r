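#' Pipeline configuration
#'
#' Bundles everything a full run needs: the simulation settings, the
#' combination grid (timeslots, selection methods, classifier families),
#' cross-validation folds, the master seed, and the output directory. A
#' run is reproducible from its persisted configuration.
#'
#' @param out_dir Output directory for the staged runs.
#' @param sim A [sim_config()].
#' @param timeslots Candidate timeslot widths in hours.
#' @param methods Selection methods (default all five).
#' @param families Classifier families (default all four).
#' @param folds Cross-validation folds.
#' @param top_k Top-app count for the usage type list.
#' @param min_tags Minimum training tags for a user to be modeled.
#' @param seed Master seed (also used when `sim$seed` is to be overridden:
#'   the simulation keeps its own seed).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("moodphone_run_"),
                       sim = sim_config(),
                       timeslots = timeslot_widths(),
                       methods = selection_methods(),
                       families = classifier_families(),
                       folds = 5, top_k = 10, min_tags = 40, seed = sim$seed) {
  structure(
    list(
      out_dir = out_dir, sim = sim, timeslots = timeslots, methods = methods,
      families = families, folds = folds, top_k = top_k, min_tags = min_tags,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

write_manifest <- function(dir, stage, payload) {
  payload$stage <- stage
  payload$package_version <- as.character(utils::packageVersion("moodphone"))
  jsonlite::write_json(payload, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
}

hash_file <- function(path) rlang::hash(readChar(path, file.size(path)))

#' Train personalized models and choose the deployed combination
#'
#' In-memory core of the training stage: validates each user's tag count,
#' builds design matrices over the candidate timeslots, evaluates the full
#' combination grid, fixes the deployed (timeslot, method, family) by
#' rank-product and average accuracy, and trains one final model per
#' (user, scale) with the chosen method's features.
#'
#' @param users Named list; each element a list with `events` (training
#'   events tibble) and `tags` (training emotion tags).
#' @param config A [run_config()].
#' @return List of class `mood_training`: `results` (combo grid tibble),
#'   `rank_table`, `choice` (a `mood_combo_choice`), `users` (per-user
#'   models, selections, usage types, training labels), `rejected`.
#' @export
train_cohort <- function(users, config) {
  checks <- vapply(users, function(u) {
    validate_training_set(u$tags, minimum = config$min_tags)$accepted
  }, logical(1))
  rejected <- names(users)[!checks]
  if (length(rejected)) {
    warn(sprintf(
      "user(s) below %d training tags rejected: %s",
      config$min_tags, paste(rejected, collapse = ", ")
    ))
  }
  users <- users[checks]
  if (length(users) == 0) {
    abort("no user passed training-set validation", class = "moodphone_validation_error")
  }
  designs <- lapply(users, function(u) {
    prepare_user_designs(u$events, u$tags, config$timeslots, config$top_k)
  })
  results <- evaluate_all_combos(
    designs, config$methods, config$families, config$folds, config$seed
  )
  rank_table <- rank_product(results)
  choice <- select_final(results)
  w_name <- as.character(choice$timeslot)
  fitted <- lapply(names(designs), function(user) {
    design <- designs[[user]][[w_name]]
    fold_seed <- derive_seed(config$seed, paste(user, "final", w_name, sep = "/"))
    per_scale <- lapply(emotion_scales(), function(scale) {
      y <- design$labels[[scale]]
      sel <- suppressWarnings(select_features(
        design$features, y, choice$method, "naive_bayes",
        config$folds,
        derive_seed(config$seed, paste(user, scale, w_name, sep = "/"))
      ))
      model <- suppressWarnings(train_model(
        mood_classifier(choice$family, seed = fold_seed),
        design$features[, sel$selected, drop = FALSE], y
      ))
      list(selection = sel, model = model)
    })
    names(per_scale) <- emotion_scales()
    list(
      user_id = user, scales = per_scale,
      usage_types = design$usage_types, width_hours = design$width_hours,
      labels = design$labels, vas = design$vas, features = design$features
    )
  })
  names(fitted) <- names(designs)
  structure(
    list(
      results = results, rank_table = rank_table, choice = choice,
      users = fitted, rejected = rejected
    ),
    class = "mood_training"
  )
}

#' @export
print.mood_training <- function(x, ...) {
  cat(sprintf(
    "<mood_training> %d users, %d combination results\n",
    length(x$users), nrow(x$results)
  ))
  print(x$choice)
  invisible(x)
}

#' Prospectively evaluate the deployed models
#'
#' For every evaluation day and every scheduled prediction time, extracts
#' the user's features over the chosen timeslot, predicts the three
#' categories, matches the user's corrected response (if any) and judges
#' success. Also scores the two benchmarks — per-scale multiple linear
#' regression and the general guess — on the same responded predictions.
#'
#' @param training A `mood_training` from [train_cohort()].
#' @param users_eval Named list (same users); each element a list with
#'   `events` (all events, training + evaluation phase), `responses`
#'   (tibble `timestamp`, `depression`, `anxiety`, `stress` of corrected
#'   ratings) and `days` (Date vector of evaluation days).
#' @return List of class `mood_evaluation_run`: `records` (prediction log),
#'   `summary` (a `mood_evaluation`), `per_scale` (per user x scale
#'   accuracy of model, linear benchmark and general guess over responded
#'   predictions).
#' @export
evaluate_cohort <- function(training, users_eval) {
  records <- list()
  per_scale <- list()
  for (user in names(training$users)) {
    tu <- training$users[[user]]
    ue <- users_eval[[user]]
    if (is.null(ue)) next
    times <- do.call(c, lapply(ue$days, schedule_predictions))
    feats <- lapply(times, function(tt) {
      extract_features(ue$events, tt, tu$width_hours, tu$usage_types)
    })
    X <- do.call(rbind, lapply(feats, as.matrix))
    preds <- lapply(emotion_scales(), function(scale) {
      predict(tu$scales[[scale]]$model, X)
    })
    names(preds) <- emotion_scales()
    lin <- suppressWarnings(benchmark_linear(tu$features, tu$vas))
    lin_pred <- predict(lin, X)
    guess <- benchmark_guess(tu$labels)
    guess_pred <- predict(guess, X)
    resp_idx <- match(round(as.numeric(times)), round(as.numeric(ue$responses$timestamp)))
    responded <- !is.na(resp_idx)
    corr <- ue$responses[resp_idx, c("depression", "anxiety", "stress")]
    corr_cat <- lapply(emotion_scales(), function(scale) {
      v <- corr[[scale]]
      out <- rep(NA_character_, length(v))
      out[!is.na(v)] <- as.character(vas_categorize(v[!is.na(v)]))
      out
    })
    names(corr_cat) <- emotion_scales()
    success <- rep(NA, length(times))
    ok <- responded
    match_all <- rep(TRUE, sum(ok))
    for (scale in emotion_scales()) {
      match_all <- match_all &
        corr_cat[[scale]][ok] == as.character(preds[[scale]][ok])
    }
    success[ok] <- match_all
    records[[user]] <- tibble::tibble(
      user_id = user, timestamp = times,
      pred_depression = preds$depression,
      pred_anxiety = preds$anxiety,
      pred_stress = preds$stress,
      corr_depression = corr$depression,
      corr_anxiety = corr$anxiety,
      corr_stress = corr$stress,
      responded = responded, success = success
    )
    for (scale in emotion_scales()) {
      truth_cat <- corr_cat[[scale]][ok]
      per_scale[[paste(user, scale)]] <- tibble::tibble(
        user_id = user, scale = scale, n = sum(ok),
        model = mean(as.character(preds[[scale]][ok]) == truth_cat),
        linear = mean(as.character(lin_pred[[scale]][ok]) == truth_cat),
        guess = mean(as.character(guess_pred[[scale]][ok]) == truth_cat)
      )
    }
  }
  records <- dplyr::bind_rows(records)
  structure(
    list(
      records = records,
      summary = summarize_evaluation(records),
      per_scale = dplyr::bind_rows(per_scale)
    ),
    class = "mood_evaluation_run"
  )
}

#' @export
print.mood_evaluation_run <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

# ---- staged, file-based runs ----------------------------------------------

#' Stage 1: simulate and write fixtures
#'
#' @param config A [run_config()].
#' @return The cohort (named list of `mood_sim_user`), invisibly; fixture
#'   files and a manifest are written under `<out_dir>/raw/<user>/`.
#' @export
run_simulate <- function(config) {
  raw_dir <- file.path(config$out_dir, "raw")
  dir.create(raw_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config$sim)
  digests <- list()
  for (id in names(cohort)) {
    paths <- write_fixture(cohort[[id]], file.path(raw_dir, id))
    digests[[id]] <- lapply(as.list(paths), hash_file)
  }
  write_manifest(raw_dir, "simulate", list(
    seed = config$sim$seed, n_users = config$sim$n_users, files = digests
  ))
  invisible(cohort)
}

read_user_fixture <- function(config, id) {
  dir <- file.path(config$out_dir, "raw", id)
  for (f in c("raw_log.csv", "tags_train.csv", "tags_eval.csv", "ground_truth.json")) {
    if (!file.exists(file.path(dir, f))) {
      abort(sprintf("missing upstream file: %s", file.path(dir, f)),
        class = "moodphone_io_error"
      )
    }
  }
  mapping <- stats::setNames(
    config$sim$app_catalog$category, config$sim$app_catalog$package
  )
  raw <- read_raw_log(file.path(dir, "raw_log.csv"))
  gt <- read_ground_truth(file.path(dir, "ground_truth.json"))
  events <- infer_usage_events(raw, mapping, config$sim$sample_period)
  list(
    events = events,
    events_train = dplyr::filter(events, .data$start < gt$eval_start),
    tags_train = read_emotion_tags(file.path(dir, "tags_train.csv")),
    responses = read_emotion_tags(file.path(dir, "tags_eval.csv")),
    eval_start = gt$eval_start
  )
}

#' Stage 2: train from fixture files
#'
#' @param config A [run_config()] whose simulate stage has run.
#' @return A `mood_training`, invisibly; combination results, rank table,
#'   chosen combination, per-user models and a manifest are written under
#'   `<out_dir>/train/`.
#' @export
run_train <- function(config) {
  raw_dir <- file.path(config$out_dir, "raw")
  if (!dir.exists(raw_dir)) {
    abort(sprintf("missing upstream directory: %s (run_simulate first)", raw_dir),
      class = "moodphone_io_error"
    )
  }
  ids <- sort(setdiff(list.dirs(raw_dir, recursive = FALSE, full.names = FALSE), ""))
  fixtures <- lapply(ids, function(id) read_user_fixture(config, id))
  names(fixtures) <- ids
  users <- lapply(fixtures, function(f) list(events = f$events_train, tags = f$tags_train))
  training <- train_cohort(users, config)
  train_dir <- file.path(config$out_dir, "train")
  dir.create(train_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(training$results, file.path(train_dir, "combo_results.csv"),
    row.names = FALSE
  )
  utils::write.csv(training$rank_table, file.path(train_dir, "rank_product.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      timeslot_hours = training$choice$timeslot,
      method = training$choice$method,
      family = training$choice$family,
      mean_accuracy = training$choice$mean_accuracy
    ),
    file.path(train_dir, "choice.json"),
    auto_unbox = TRUE, digits = NA
  )
  saveRDS(training, file.path(train_dir, "training.rds"))
  selected <- lapply(training$users, function(u) {
    lapply(u$scales, function(s) s$selection$selected)
  })
  jsonlite::write_json(selected, file.path(train_dir, "selected_features.json"),
    auto_unbox = FALSE, pretty = TRUE
  )
  write_manifest(train_dir, "train", list(
    seed = config$seed, users = names(training$users),
    rejected = training$rejected,
    choice = list(
      timeslot_hours = training$choice$timeslot,
      method = training$choice$method, family = training$choice$family
    )
  ))
  invisible(training)
}

#' Stage 3: evaluate from fixture files and trained models
#'
#' @param config A [run_config()] whose simulate and train stages have run.
#' @return A `mood_evaluation_run`, invisibly; the prediction log, the
#'   accounting summary, the benchmark table and a manifest are written
#'   under `<out_dir>/evaluate/`.
#' @export
run_evaluate <- function(config) {
  train_path <- file.path(config$out_dir, "train", "training.rds")
  if (!file.exists(train_path)) {
    abort(sprintf("missing upstream file: %s (run_train first)", train_path),
      class = "moodphone_io_error"
    )
  }
  training <- readRDS(train_path)
  users_eval <- lapply(names(training$users), function(id) {
    f <- read_user_fixture(config, id)
    days <- as.Date(f$eval_start) + seq_len(config$sim$n_days_eval) - 1
    list(events = f$events, responses = f$responses, days = days)
  })
  names(users_eval) <- names(training$users)
  run <- evaluate_cohort(training, users_eval)
  eval_dir <- file.path(config$out_dir, "evaluate")
  dir.create(eval_dir, recursive = TRUE, showWarnings = FALSE)
  log_df <- dplyr::mutate(run$records, timestamp = format_iso(.data$timestamp))
  utils::write.csv(log_df, file.path(eval_dir, "prediction_log.csv"), row.names = FALSE)
  utils::write.csv(run$summary$per_user, file.path(eval_dir, "summary_per_user.csv"),
    row.names = FALSE
  )
  utils::write.csv(run$summary$cohort, file.path(eval_dir, "summary_cohort.csv"),
    row.names = FALSE
  )
  utils::write.csv(run$per_scale, file.path(eval_dir, "benchmarks.csv"),
    row.names = FALSE
  )
  write_manifest(eval_dir, "evaluate", list(
    seed = config$seed,
    n_predictions = nrow(run$records),
    mean_accuracy = run$summary$cohort$mean_accuracy
  ))
  invisible(run)
}

#' Run all three stages
#'
#' @param config A [run_config()].
#' @return List with `cohort`, `training`, `evaluation`.
#' @export
run_pipeline <- function(config) {
  cohort <- run_simulate(config)
  training <- run_train(config)
  evaluation <- run_evaluate(config)
  list(cohort = cohort, training = training, evaluation = evaluation)
}
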