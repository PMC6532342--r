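# Constrained trial generator.
#
# A playable trial is a sequence of 4 consecutive single-target boards:
# the initial board and each board reached by solving the unique valid
# move and refilling must (a) contain no pre-existing run, (b) admit
# exactly one valid move, and (c) have that move create exactly one run
# of exactly three tiles (so the hint and the per-board search time are
# unambiguous). Boards are found by rejection sampling; refills are
# searched depth-first with per-stage retry budgets and backtracking.

#' Generator configuration
#'
#' @param max_board_attempts Rejection-sampling budget for a
#'   single-target board (default 10000 raw samples).
#' @param max_refill_attempts Refill samples per stage before
#'   backtracking (default 2000).
#' @param forbid_runs_gt3 Require the unique move to create exactly one
#'   run of exactly length 3 (default `TRUE`).
#' @param trials_required Playable-trial threshold used by
#'   [survey_playability()] to call a level feasible (default 47).
#' @param max_restarts Full restarts (fresh initial board) of the refill
#'   search before [generate_trial()] gives up (default 25).
#' @return A list of class `smt_generator_config`.
#' @export
generator_config <- function(max_board_attempts = 10000L,
                             max_refill_attempts = 2000L,
                             forbid_runs_gt3 = TRUE,
                             trials_required = 47L,
                             max_restarts = 25L) {
  structure(
    list(
      max_board_attempts = as_count(max_board_attempts, "max_board_attempts"),
      max_refill_attempts = as_count(max_refill_attempts,
                                     "max_refill_attempts"),
      forbid_runs_gt3 = isTRUE(forbid_runs_gt3),
      trials_required = as_count(trials_required, "trials_required"),
      max_restarts = as_count(max_restarts, "max_restarts")
    ),
    class = "smt_generator_config"
  )
}

# Single-target acceptance test on a bare matrix. Returns NULL on
# rejection, else the unique canonical solution move.
accept_board_mat <- function(m, forbid_runs_gt3 = TRUE) {
  if (cpp_has_run(m)) return(NULL)
  mv <- cpp_valid_moves(m, 2L)
  if (nrow(mv) != 1L) return(NULL)
  sol <- as.integer(mv[1, ])
  if (forbid_runs_gt3) {
    st <- cpp_swap_run_stats(m, sol[1], sol[2], sol[3], sol[4])
    if (st[1] != 1L || st[2] != 3L) return(NULL)
  }
  sol
}

sample_board_mat <- function(w, h, t) {
  matrix(sample.int(t, w * h, replace = TRUE) - 1L, nrow = h, ncol = w)
}

#' Generate a random stable board
#'
#' Rejection-samples uniform random boards until one with no run is
#' found. No constraint is placed on the number of valid moves; use
#' [generate_stable_single_target_board()] for single-target boards.
#'
#' @param level A level: `c(w, h, t)`, or anything with `$w`, `$h`, `$t`.
#' @param seed Optional integer seed (the caller's RNG state is
#'   preserved).
#' @param max_attempts Sampling budget.
#' @return An [smt_board()], or an `smt_gen_failure` if the budget is
#'   exhausted.
#' @export
random_stable_board <- function(level, seed = NULL, max_attempts = 10000L) {
  lv <- as_level(level)
  with_seed_if(seed, {
    for (i in seq_len(max_attempts)) {
      m <- sample_board_mat(lv$w, lv$h, lv$t)
      if (!has_run_mat(m)) return(smt_board(m, lv$t))
    }
    gen_failure("no stable board found", max_attempts, lv)
  })
}

gen_failure <- function(reason, attempts, level, stage = NA_integer_) {
  structure(
    list(reason = reason, attempts = attempts, level = level, stage = stage),
    class = "smt_gen_failure"
  )
}

#' @export
print.smt_gen_failure <- function(x, ...) {
  cat(sprintf("<smt_gen_failure> %s (w=%d h=%d t=%d, %d attempts%s)\n",
              x$reason, x$level$w, x$level$h, x$level$t, x$attempts,
              if (is.na(x$stage)) "" else sprintf(", stage %d", x$stage)))
  invisible(x)
}

#' Did a generator call fail?
#'
#' @param x Result of [generate_trial()],
#'   [generate_stable_single_target_board()] or [random_stable_board()].
#' @return `TRUE` for an `smt_gen_failure`.
#' @export
is_gen_failure <- function(x) inherits(x, "smt_gen_failure")

#' Generate a single-target board
#'
#' Uniform random boards are sampled and accepted when they are stable,
#' admit exactly one valid move, and (by default) that move creates
#' exactly one run of exactly three tiles. Levels with large set size and
#' few tile types have vanishing acceptance probability — random boards
#' there carry many target patterns — so the budget can be exhausted;
#' that outcome is reported as a failure value, not an error.
#'
#' @inheritParams random_stable_board
#' @param config A [generator_config()].
#' @return An [smt_board()] with attributes `solution` (the unique
#'   canonical move) and `attempts`, or an `smt_gen_failure`.
#' @export
generate_stable_single_target_board <- function(level, seed = NULL,
                                                config = generator_config()) {
  lv <- as_level(level)
  with_seed_if(seed, {
    for (i in seq_len(config$max_board_attempts)) {
      m <- sample_board_mat(lv$w, lv$h, lv$t)
      sol <- accept_board_mat(m, config$forbid_runs_gt3)
      if (!is.null(sol)) {
        b <- smt_board(m, lv$t)
        attr(b, "solution") <- sol
        attr(b, "attempts") <- i
        return(b)
      }
    }
    gen_failure("single-target board budget exhausted",
                config$max_board_attempts, lv)
  })
}

# Removal bookkeeping after solving `sol` on matrix `m`: the collapsed
# matrix with NA holes at the top and the per-column refill demand.
solve_and_collapse <- function(m, sol) {
  tmp <- m[sol[1], sol[2]]
  m[sol[1], sol[2]] <- m[sol[3], sol[4]]
  m[sol[3], sol[4]] <- tmp
  rm <- removal_mask_mat(m)
  list(holes = collapse_mat(m, rm), need = colSums(rm))
}

# Reconstruct per-column refill streams from a filled board and the
# hole positions (column-major, so within a column tiles come top-down:
# first stream element ends highest, as resolve_match expects).
split_refill <- function(filled, hole_idx, h, w) {
  cols <- (hole_idx - 1L) %/% h + 1L
  vals <- filled[hole_idx]
  out <- rep(list(integer(0)), w)
  for (cc in unique(cols)) out[[cc]] <- vals[cols == cc]
  out
}

#' Generate a playable trial
#'
#' Searches for a sequence of 4 consecutive single-target boards. The
#' initial board comes from rejection sampling
#' ([generate_stable_single_target_board()]); after each of the first
#' three solves, refill tiles are sampled uniformly and retried up to the
#' per-stage budget until the refilled board again passes the
#' single-target acceptance test, backtracking one stage when a budget is
#' exhausted and restarting from a fresh initial board after repeated
#' stage failure. The fourth match needs no refill for gameplay, but a
#' (sampled) refill is stored for uniformity. Deterministic given `seed`.
#'
#' @inheritParams generate_stable_single_target_board
#' @return An `smt_trial` (see [validate_trial()] for its contract), or
#'   an `smt_gen_failure` with the stage reached and attempt counts.
#' @export
generate_trial <- function(level, seed = NULL, config = generator_config()) {
  lv <- as_level(level)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max - 1L, 1L)
  }
  seed <- as.integer(seed)
  withr::with_seed(seed, {
    counter <- new.env(parent = emptyenv())

    dfs <- function(m, sol, stage) {
      step <- solve_and_collapse(m, sol)
      holes <- step$holes
      hole_idx <- which(is.na(holes))
      n_holes <- length(hole_idx)
      if (stage == 4L) {
        filled <- holes
        filled[hole_idx] <- sample.int(lv$t, n_holes, replace = TRUE) - 1L
        refill <- split_refill(filled, hole_idx, nrow(m), ncol(m))
        return(list(list(move = sol, refill = refill)))
      }
      for (a in seq_len(config$max_refill_attempts)) {
        counter$checks <- counter$checks + 1L
        if (counter$checks > 4L * config$max_refill_attempts) return(NULL)
        nxt <- holes
        nxt[hole_idx] <- sample.int(lv$t, n_holes, replace = TRUE) - 1L
        nxt_sol <- accept_board_mat(nxt, config$forbid_runs_gt3)
        if (is.null(nxt_sol)) next
        rest <- dfs(nxt, nxt_sol, stage + 1L)
        if (!is.null(rest)) {
          refill <- split_refill(nxt, hole_idx, nrow(m), ncol(m))
          return(c(list(list(move = sol, refill = refill)), rest))
        }
      }
      NULL
    }

    for (restart in seq_len(config$max_restarts)) {
      b <- generate_stable_single_target_board(lv, seed = NULL,
                                               config = config)
      if (is_gen_failure(b)) {
        b$stage <- 1L
        return(b)
      }
      counter$checks <- 0L
      matches <- dfs(board_matrix(b), attr(b, "solution"), 1L)
      if (!is.null(matches)) {
        return(new_trial(lv, b, matches, seed))
      }
    }
    gen_failure("refill search exhausted all restarts",
                config$max_restarts, lv, stage = 2L)
  })
}

new_trial <- function(lv, initial_board, matches, seed, trial_id = NULL) {
  initial <- smt_board(board_matrix(initial_board), lv$t)
  structure(
    list(
      level = lv,
      trial_id = trial_id %||%
        sprintf("w%d-h%d-t%d-s%d", lv$w, lv$h, lv$t, seed),
      seed = as.integer(seed),
      initial_board = initial,
      matches = matches
    ),
    class = "smt_trial"
  )
}

#' @export
print.smt_trial <- function(x, ...) {
  cat(sprintf("<smt_trial %s: %dx%d board, %d tile types, %d matches>\n",
              x$trial_id, x$level$w, x$level$h, x$level$t,
              length(x$matches)))
  invisible(x)
}

#' Replay a trial's board sequence
#'
#' Derives the four single-target boards of a trial by repeatedly
#' applying the stored solution move and refill.
#'
#' @param trial An `smt_trial`.
#' @return A list of 4 [smt_board()] objects.
#' @export
trial_boards <- function(trial) {
  b <- trial$initial_board
  out <- vector("list", length(trial$matches))
  for (i in seq_along(trial$matches)) {
    out[[i]] <- b
    if (i < length(trial$matches)) {
      b <- resolve_match(apply_swap(b, trial$matches[[i]]$move),
                         trial$matches[[i]]$refill)
    }
  }
  out
}

#' Generate a bank of distinct playable trials
#'
#' Calls [generate_trial()] (with seeds drawn from the seeded stream)
#' until `n` trials with distinct initial boards are collected or the
#' call budget runs out.
#'
#' @inheritParams generate_trial
#' @param n Number of distinct trials wanted.
#' @param max_calls Generator-call budget (default `4 * n`).
#' @return A list of `smt_trial`s. Fewer than `n` (with a warning) when
#'   the budget is exhausted first.
#' @export
generate_trials <- function(level, n, seed = NULL,
                            config = generator_config(), max_calls = NULL) {
  n <- as_count(n, "n")
  max_calls <- max_calls %||% (4L * n)
  with_seed_if(seed, {
    out <- list()
    seen <- character(0)
    for (call in seq_len(max_calls)) {
      tr <- generate_trial(level, seed = NULL, config = config)
      if (is_gen_failure(tr)) next
      key <- paste(board_matrix(tr$initial_board), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- tr
      if (length(out) >= n) break
    }
    if (length(out) < n) {
      warning(sprintf("found %d of %d requested trials within the budget",
                      length(out), n), call. = FALSE)
    }
    out
  })
}

#' Survey per-level playability
#'
#' For each level, repeatedly runs [generate_trial()] (trial seeds drawn
#' from the seeded stream) and counts distinct playable trials —
#' distinctness meaning distinct initial boards — until the
#' `trials_required` threshold is reached, a generation attempt exhausts
#' its budget, or `max_calls` calls have been made. A level is feasible
#' when at least `trials_required` distinct playable trials were found.
#'
#' @param levels Tibble of levels (columns `w`, `h`, `t`), e.g. from
#'   [enumerate_level_specs()].
#' @param config A [generator_config()].
#' @param seed Integer seed driving the whole survey.
#' @param max_calls Cap on generator calls per level (default
#'   `2 * trials_required`).
#' @param cache_file Optional CSV path; when it exists it is read and
#'   returned, otherwise results are computed and written there.
#' @return A tibble of class `smt_survey`: `level_id`, `w`, `h`, `t`,
#'   `set_size`, `n_playable`, `feasible`.
#' @export
survey_playability <- function(levels, config = generator_config(),
                               seed = 1L, max_calls = NULL,
                               cache_file = NULL) {
  if (!is.null(cache_file) && file.exists(cache_file)) {
    out <- readr::read_csv(cache_file, show_col_types = FALSE)
    class(out) <- c("smt_survey", class(out))
    return(out)
  }
  max_calls <- max_calls %||% (2L * config$trials_required)
  rows <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(nrow(levels)), function(i) {
      lv <- as_level(levels[i, ])
      seen <- character(0)
      for (call in seq_len(max_calls)) {
        tr <- generate_trial(lv, seed = NULL, config = config)
        if (is_gen_failure(tr)) break
        seen <- union(seen, paste(board_matrix(tr$initial_board),
                                  collapse = ","))
        if (length(seen) >= config$trials_required) break
      }
      tibble(level_id = sprintf("w%d_h%d_t%d", lv$w, lv$h, lv$t),
             w = lv$w, h = lv$h, t = lv$t, set_size = lv$set_size,
             n_playable = length(seen),
             feasible = length(seen) >= config$trials_required)
    })
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(cache_file)) {
    readr::write_csv(out, cache_file)
  }
  class(out) <- c("smt_survey", class(out))
  out
}

#' Plot a playability survey
#'
#' Tile map of the level space: number of playable trials found per
#' `(w, h, t)` cell, feasible cells outlined.
#'
#' @param object An `smt_survey` from [survey_playability()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smt_survey <- function(object, ...) {
  df <- dplyr::mutate(object, size = sprintf("%dx%d", .data$w, .data$h))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$size,
                                   fill = .data$n_playable)) +
    ggplot2::geom_tile(ggplot2::aes(color = .data$feasible),
                       linewidth = 0.6) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "black",
                                           `FALSE` = "grey80")) +
    ggplot2::labs(x = "tile types (t)", y = "board size (w x h)",
                  fill = "playable\ntrials", color = "feasible") +
    ggplot2::theme_minimal()
}
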