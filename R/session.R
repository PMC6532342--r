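# Headless gameplay with move-level logging.
#
# A session plays one validated trial. Timing is injected: every move
# submission carries the elapsed time (seconds) since the board became
# active or since the previous move, so the engine is equally usable
# from a GUI front end, a script, or the synthetic player. One log row
# is emitted per attempted swap; malformed inputs (out-of-bounds or
# non-adjacent cells) are rejected with an error and never logged,
# because only genuine swap attempts count as moves. Swapping two
# identical tiles is a genuine (if futile) swap attempt and is logged as
# a false move.

LOG_COLUMNS <- c("participant_id", "group", "w", "h", "t", "trial_id",
                 "board_index", "move_number", "r1", "c1", "r2", "c2",
                 "elapsed_time", "accuracy", "hint_used",
                 "difficulty_rating")

#' Start a session on a trial
#'
#' Validates the trial (replay check), activates board 1 and returns a
#' mutable session object. A session is single-use: it cannot be
#' restarted.
#'
#' @param trial An `smt_trial`.
#' @param participant_id,group Metadata copied into every log row.
#' @param validate Run [validate_trial()] first (default `TRUE`).
#' @return An object of class `smt_session`.
#' @seealso [submit_move()], [request_hint()], [session_log()]
#' @export
start_trial <- function(trial, participant_id = "p01",
                        group = NA_character_, validate = TRUE) {
  if (validate) {
    report <- validate_trial(trial)
    if (!report$ok) {
      stop("refusing to start invalid trial: ",
           report$violations$message[1], call. = FALSE)
    }
    boards <- report$boards
  } else {
    boards <- trial_boards(trial)
  }
  s <- new.env(parent = emptyenv())
  s$trial <- trial
  s$boards <- boards
  s$stage <- 1L
  s$move_number <- 0L
  s$hint_armed <- FALSE
  s$finished <- FALSE
  s$rating <- NA_integer_
  s$participant_id <- as.character(participant_id)
  s$group <- as.character(group)
  s$log <- list()
  class(s) <- "smt_session"
  s
}

#' @export
print.smt_session <- function(x, ...) {
  cat(sprintf("<smt_session %s: %s, board %d/4, %d moves logged>\n",
              x$participant_id, x$trial$trial_id,
              min(x$stage, 4L), length(x$log)))
  invisible(x)
}

#' Currently active board of a session
#'
#' @param session An `smt_session`.
#' @return The active [smt_board()], or `NULL` once the trial is
#'   complete.
#' @export
current_board <- function(session) {
  if (session$finished) return(NULL)
  session$boards[[session$stage]]
}

#' @rdname current_board
#' @export
is_finished <- function(session) session$finished

log_entry <- function(session, move, elapsed, accuracy, hint_used) {
  lv <- session$trial$level
  session$move_number <- session$move_number + 1L
  session$log[[length(session$log) + 1L]] <- tibble(
    participant_id = session$participant_id,
    group = session$group,
    w = lv$w, h = lv$h, t = lv$t,
    trial_id = session$trial$trial_id,
    board_index = session$stage,
    move_number = session$move_number,
    r1 = move[1], c1 = move[2], r2 = move[3], c2 = move[4],
    elapsed_time = elapsed,
    accuracy = accuracy,
    hint_used = hint_used,
    difficulty_rating = NA_integer_
  )
}

#' Submit a move to a session
#'
#' If the move is the board's unique valid move it is logged as correct,
#' the match resolves, and the next board becomes active (the trial is
#' self-terminating after the fourth correct move). Any other adjacent
#' swap bounces: the board is unchanged and a false move is logged.
#' Out-of-bounds or non-adjacent cells are malformed input and raise an
#' error without logging.
#'
#' @param session An `smt_session`.
#' @param move Integer vector `c(r1, c1, r2, c2)`.
#' @param elapsed Seconds since the board became active or since the
#'   previous move; must be positive.
#' @return One of `"matched"`, `"bounce"`, `"complete"`.
#' @export
submit_move <- function(session, move, elapsed) {
  if (session$finished) stop("trial already complete", call. = FALSE)
  if (!is.numeric(elapsed) || length(elapsed) != 1L || !is.finite(elapsed) ||
      elapsed <= 0) {
    stop("`elapsed` must be a positive number of seconds", call. = FALSE)
  }
  move <- canonical_move(move)
  lv <- session$trial$level
  if (any(move[c(1, 3)] < 1L) || any(move[c(1, 3)] > lv$h) ||
      any(move[c(2, 4)] < 1L) || any(move[c(2, 4)] > lv$w)) {
    stop("malformed move: cells out of bounds", call. = FALSE)
  }
  if (!is_adjacent_move(move)) {
    stop("malformed move: cells not orthogonally adjacent", call. = FALSE)
  }
  solution <- canonical_move(session$trial$matches[[session$stage]]$move)
  if (all(move == solution)) {
    log_entry(session, move, elapsed, "correct", session$hint_armed)
    session$hint_armed <- FALSE
    session$move_number <- 0L
    if (session$stage == 4L) {
      session$finished <- TRUE
      "complete"
    } else {
      session$stage <- session$stage + 1L
      "matched"
    }
  } else {
    log_entry(session, move, elapsed, "false", FALSE)
    "bounce"
  }
}

#' Request a hint for the active board
#'
#' Returns the board's unique valid move and marks the board as hinted:
#' the eventual correct move on this board is logged with
#' `hint_used = TRUE`. The board does not advance.
#'
#' @param session An `smt_session`.
#' @return The hint move `c(r1, c1, r2, c2)`, invisibly.
#' @export
request_hint <- function(session) {
  if (session$finished) stop("trial already complete", call. = FALSE)
  session$hint_armed <- TRUE
  invisible(canonical_move(session$trial$matches[[session$stage]]$move))
}

#' Attach a difficulty rating to a completed trial
#'
#' After the trial is complete the player rates its difficulty on a
#' 10-point scale from 1 (very easy) to 10 (very difficult); the rating
#' is attached to every log row of the trial.
#'
#' @param session A finished `smt_session`.
#' @param rating Integer 1-10.
#' @return The session, invisibly.
#' @export
record_difficulty_rating <- function(session, rating) {
  if (!session$finished) {
    stop("difficulty is rated after the trial is complete", call. = FALSE)
  }
  rating <- as_count(rating, "rating")
  if (rating < 1L || rating > 10L) {
    stop("`rating` must be between 1 and 10", call. = FALSE)
  }
  session$rating <- rating
  invisible(session)
}

#' Extract the move log of a session
#'
#' @param session An `smt_session`.
#' @return A tibble with one row per attempted move, fixed column order:
#'   participant_id, group, w, h, t, trial_id, board_index, move_number,
#'   r1, c1, r2, c2, elapsed_time, accuracy, hint_used,
#'   difficulty_rating.
#' @export
session_log <- function(session) {
  if (length(session$log) == 0L) {
    out <- tibble(
      participant_id = character(0), group = character(0),
      w = integer(0), h = integer(0), t = integer(0),
      trial_id = character(0), board_index = integer(0),
      move_number = integer(0), r1 = integer(0), c1 = integer(0),
      r2 = integer(0), c2 = integer(0), elapsed_time = numeric(0),
      accuracy = character(0), hint_used = logical(0),
      difficulty_rating = integer(0)
    )
    return(out)
  }
  out <- dplyr::bind_rows(session$log)
  if (!is.na(session$rating)) out$difficulty_rating <- session$rating
  out[, LOG_COLUMNS]
}

#' Read or write a move log CSV
#'
#' One row per attempted move, fixed header and column order as in
#' [session_log()].
#'
#' @param log A move-log tibble.
#' @param path CSV file path.
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` the log tibble.
#' @export
write_session_log <- function(log, path) {
  stopifnot(all(LOG_COLUMNS %in% names(log)))
  readr::write_csv(log[, LOG_COLUMNS], path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant_id = readr::col_character(),
                    group = readr::col_character(),
                    trial_id = readr::col_character(),
                    accuracy = readr::col_character(),
                    hint_used = readr::col_logical(),
                    .default = readr::col_number()
                  ))
}

#' Seed-deterministic level ordering
#'
#' Shuffles a level table into the presentation order of a test block;
#' random order avoids the learning effects an incremental order would
#' invite. Deterministic given `seed`.
#'
#' @param levels A tibble of levels.
#' @param seed Integer seed.
#' @return The shuffled tibble.
#' @export
randomize_level_order <- function(levels, seed) {
  withr::with_seed(as.integer(seed),
                   levels[sample.int(nrow(levels)), , drop = FALSE])
}
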