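# Synthetic player: a fixture generator with known ground truth.
#
# Simulated search times follow a gamma distribution whose mean is
# linear in set size (positive coefficient) and number of tile types
# (negative coefficient), scaled by a per-group multiplier — the minimal
# structure consistent with the effect directions the task is built to
# measure (search time grows with set size, shrinks with distractor
# heterogeneity, grows with age-group). It is a test fixture, not a
# cognitive model.

#' Define a synthetic player
#'
#' Mean search time on a `(w, h, t)` board is
#' `mu = group_multiplier * max(eps, base_time + set_size_effect * w * h
#' + tile_type_effect * t)`; the realized time is gamma with that mean
#' and shape `shape`. With probability `p_false` the player first emits
#' one false move (a random non-solution adjacent swap) that splits the
#' search time; with probability `p_hint` the board is solved after a
#' hint.
#'
#' Defaults emulate a fast adult player: around 2.5 s mean search time
#' on a 5x5 board with 5 tile types, rare false moves and hints.
#'
#' @param base_time Baseline seconds (`>= 0`).
#' @param set_size_effect Seconds per display item (`>= 0`).
#' @param tile_type_effect Seconds per additional tile type (`<= 0`).
#' @param group_multiplier Positive scalar; slower groups have larger
#'   multipliers.
#' @param shape Gamma shape parameter `k > 0` (default 4); smaller values
#'   give more skew.
#' @param p_false,p_hint Per-board probabilities in `[0, 1]`.
#' @param label Group label written into simulated logs.
#' @param eps Floor on the linear predictor so the mean stays positive.
#' @return A list of class `smt_player_model`.
#' @export
player_model <- function(base_time = 1.0, set_size_effect = 0.08,
                         tile_type_effect = -0.1, group_multiplier = 1,
                         shape = 4, p_false = 0.02, p_hint = 0.03,
                         label = "player", eps = 0.05) {
  stopifnot(base_time >= 0, set_size_effect >= 0, tile_type_effect <= 0,
            group_multiplier > 0, shape > 0,
            p_false >= 0, p_false <= 1, p_hint >= 0, p_hint <= 1, eps > 0)
  structure(
    list(base_time = base_time, set_size_effect = set_size_effect,
         tile_type_effect = tile_type_effect,
         group_multiplier = group_multiplier, shape = shape,
         p_false = p_false, p_hint = p_hint, label = as.character(label),
         eps = eps),
    class = "smt_player_model"
  )
}

#' @export
print.smt_player_model <- function(x, ...) {
  cat(sprintf(
    "<smt_player_model '%s': mu = %.2f x max(%.2f, %.2f + %.3f*set_size %+.3f*t), k=%.1f>\n",
    x$label, x$group_multiplier, x$eps, x$base_time, x$set_size_effect,
    x$tile_type_effect, x$shape))
  invisible(x)
}

#' Read a player model from a YAML or JSON config file
#'
#' The file holds any subset of [player_model()]'s arguments.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `smt_player_model`.
#' @export
read_player_model <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(player_model, cfg)
}

player_mean_time <- function(model, w, h, t) {
  model$group_multiplier *
    pmax(model$eps,
         model$base_time + model$set_size_effect * (w * h) +
           model$tile_type_effect * t)
}

# One simulated board worth of log entries, without a session engine:
# used for large-scale metric recovery where only (w, h, t) matters.
# `solution` supplies real move coordinates when available.
#' Simulate one board's move-log entries
#'
#' Draws the board's total search time from a gamma distribution with
#' the model's mean and shape, optionally splits off a false move and/or
#' flags hint use, and returns log rows ending in the correct move. Pass
#' a real `solution` (and `board`) to get true move coordinates;
#' otherwise placeholder coordinates are used, which is sufficient for
#' time- and accuracy-based metrics.
#'
#' @param model An [player_model()].
#' @param w,h,t Board context: width, height, tile types.
#' @param solution Optional true move `c(r1, c1, r2, c2)`.
#' @param participant_id,trial_id,board_index Metadata for the log rows.
#' @return A move-log tibble (same columns as [session_log()]).
#' @export
simulate_board <- function(model, w, h, t, solution = NULL,
                           participant_id = "sim01", trial_id = "sim",
                           board_index = 1L) {
  stopifnot(inherits(model, "smt_player_model"))
  mu <- player_mean_time(model, w, h, t)
  total <- rgamma(1L, shape = model$shape, rate = model$shape / mu)
  total <- max(total, 1e-3)
  hint <- runif(1L) < model$p_hint
  false_first <- runif(1L) < model$p_false
  solution <- if (is.null(solution)) c(1L, 1L, 1L, 2L) else
    canonical_move(solution)
  base <- tibble(
    participant_id = participant_id, group = model$label,
    w = as.integer(w), h = as.integer(h), t = as.integer(t),
    trial_id = trial_id, board_index = as.integer(board_index),
    move_number = 1L,
    r1 = solution[1], c1 = solution[2], r2 = solution[3], c2 = solution[4],
    elapsed_time = total, accuracy = "correct", hint_used = hint,
    difficulty_rating = NA_integer_
  )
  if (!false_first) return(base)
  frac <- runif(1L, 0.2, 0.8)
  wrong <- random_wrong_move(w, h, solution)
  false_row <- base
  false_row$elapsed_time <- total * frac
  false_row$accuracy <- "false"
  false_row$hint_used <- FALSE
  false_row[, c("r1", "c1", "r2", "c2")] <- as.list(wrong)
  base$elapsed_time <- total * (1 - frac)
  base$move_number <- 2L
  dplyr::bind_rows(false_row, base)
}

# A random adjacent swap different from the solution. With exactly one
# valid move on the board, any other adjacent pair is a false move.
random_wrong_move <- function(w, h, solution) {
  repeat {
    r <- sample.int(h, 1L)
    cc <- sample.int(w, 1L)
    horiz <- runif(1L) < 0.5
    mv <- if (horiz && cc < w) c(r, cc, r, cc + 1L) else
      if (!horiz && r < h) c(r, cc, r + 1L, cc) else next
    mv <- canonical_move(mv)
    if (!all(mv == solution)) return(mv)
  }
}

#' Simulate a cohort playing a trial set
#'
#' Each simulated participant plays every trial through the session
#' engine ([start_trial()]/[submit_move()]), so the resulting logs
#' satisfy the replay property: every correct move is the unique valid
#' move of its board. Deterministic given `seed`.
#'
#' @param models A list of [player_model()]s, one per group.
#' @param trials A list of validated `smt_trial`s.
#' @param n_per_group Participants simulated per model (default 1).
#' @param seed Optional integer seed.
#' @return A combined move-log tibble.
#' @export
simulate_cohort <- function(models, trials, n_per_group = 1L, seed = NULL) {
  if (inherits(models, "smt_player_model")) models <- list(models)
  if (inherits(trials, "smt_trial")) trials <- list(trials)
  if (length(models) < 1L) stop("need at least one player model",
                                call. = FALSE)
  if (length(trials) < 1L) stop("need at least one trial", call. = FALSE)
  ok_model <- vapply(models, inherits, logical(1), "smt_player_model")
  ok_trial <- vapply(trials, inherits, logical(1), "smt_trial")
  if (!all(ok_model)) stop("`models` must be player_model() objects",
                           call. = FALSE)
  if (!all(ok_trial)) {
    stop("`trials` must be smt_trial objects (did a generation attempt fail?)",
         call. = FALSE)
  }
  n_per_group <- as_count(n_per_group, "n_per_group")
  with_seed_if(seed, {
    logs <- list()
    for (model in models) {
      for (j in seq_len(n_per_group)) {
        pid <- sprintf("%s_%02d", model$label, j)
        for (trial in trials) {
          logs[[length(logs) + 1L]] <-
            simulate_session(model, trial, pid)
        }
      }
    }
    dplyr::bind_rows(logs)
  })
}

# Play one trial via the session engine under the player model.
simulate_session <- function(model, trial, participant_id) {
  s <- start_trial(trial, participant_id = participant_id,
                   group = model$label, validate = FALSE)
  lv <- trial$level
  mu <- player_mean_time(model, lv$w, lv$h, lv$t)
  while (!is_finished(s)) {
    total <- max(rgamma(1L, shape = model$shape, rate = model$shape / mu),
                 1e-3)
    solution <- canonical_move(trial$matches[[s$stage]]$move)
    if (runif(1L) < model$p_hint) request_hint(s)
    if (runif(1L) < model$p_false) {
      frac <- runif(1L, 0.2, 0.8)
      submit_move(s, random_wrong_move(lv$w, lv$h, solution), total * frac)
      total <- total * (1 - frac)
    }
    submit_move(s, solution, total)
  }
  record_difficulty_rating(s, sample.int(10L, 1L))
  session_log(s)
}
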