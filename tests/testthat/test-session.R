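# Headless session engine: bounce rule, hints, logging, ratings.

play_correct <- function(s, tr, elapsed = 1.5) {
  submit_move(s, tr$matches[[s$stage]]$move, elapsed)
}

test_that("a session starts on board 1 with an empty log", {
  tr <- trial_bank()[[1]]
  s <- start_trial(tr, participant_id = "px", group = "young")
  expect_identical(board_matrix(current_board(s)),
                   board_matrix(tr$initial_board))
  expect_equal(nrow(session_log(s)), 0L)
  expect_false(is_finished(s))
})

test_that("invalid trials are refused at session start", {
  tr <- trial_bank()[[1]]
  bad <- tr
  bad$matches <- bad$matches[1:2]
  expect_error(start_trial(bad), "refusing")
})

test_that("correct moves advance, other swaps bounce, trials self-terminate", {
  tr <- trial_bank()[[1]]
  s <- start_trial(tr)
  boards <- trial_boards(tr)

  # a wrong adjacent swap bounces and is logged as a false move
  sol <- tr$matches[[1]]$move
  wrong <- searchmatch:::random_wrong_move(4, 4, searchmatch:::canonical_move(sol))
  expect_equal(submit_move(s, wrong, 0.9), "bounce")
  expect_identical(board_matrix(current_board(s)),
                   board_matrix(tr$initial_board))
  log <- session_log(s)
  expect_equal(log$accuracy, "false")
  expect_equal(log$move_number, 1L)

  # the unique move matches and loads board 2
  expect_equal(play_correct(s, tr), "matched")
  expect_identical(board_matrix(current_board(s)),
                   board_matrix(boards[[2]]))

  expect_equal(play_correct(s, tr), "matched")
  expect_equal(play_correct(s, tr), "matched")
  expect_equal(play_correct(s, tr), "complete")
  expect_true(is_finished(s))
  expect_null(current_board(s))
  expect_error(submit_move(s, tr$matches[[4]]$move, 1), "complete")

  # per board exactly one correct entry, and it is the last for the board
  log <- session_log(s)
  by_board <- split(log, log$board_index)
  for (d in by_board) {
    expect_equal(sum(d$accuracy == "correct"), 1L)
    expect_equal(d$accuracy[nrow(d)], "correct")
  }
})

test_that("malformed submissions error without being logged", {
  tr <- trial_bank()[[1]]
  s <- start_trial(tr)
  expect_error(submit_move(s, c(1, 1, 3, 1), 1), "adjacent")
  expect_error(submit_move(s, c(0, 1, 1, 1), 1), "bounds")
  expect_error(submit_move(s, c(4, 4, 4, 5), 1), "bounds")
  expect_error(submit_move(s, tr$matches[[1]]$move, 0), "positive")
  expect_error(submit_move(s, tr$matches[[1]]$move, -2), "positive")
  expect_equal(nrow(session_log(s)), 0L)
})

test_that("hints reveal the unique move and flag the correct entry", {
  tr <- trial_bank()[[1]]
  s <- start_trial(tr)
  hint <- request_hint(s)
  expect_equal(unname(hint),
               searchmatch:::canonical_move(tr$matches[[1]]$move))
  # the hint does not advance the board
  expect_identical(board_matrix(current_board(s)),
                   board_matrix(tr$initial_board))
  submit_move(s, hint, 2.0)
  log <- session_log(s)
  expect_true(log$hint_used[log$accuracy == "correct"])
  # board 2 without hint
  play_correct(s, tr)
  log <- session_log(s)
  expect_false(log$hint_used[log$board_index == 2][1])
})

test_that("hint on the worked example board reveals its only swap", {
  # wrap board W into a one-shot pseudo-trial via direct move comparison
  expect_equal(unlist(enumerate_valid_moves(board_w())[1, ],
                      use.names = FALSE),
               c(4L, 3L, 4L, 4L))
})

test_that("difficulty ratings attach to completed trials only", {
  tr <- trial_bank()[[1]]
  s <- start_trial(tr)
  expect_error(record_difficulty_rating(s, 5), "complete")
  for (i in 1:4) play_correct(s, tr)
  expect_error(record_difficulty_rating(s, 0), ">= 1")
  expect_error(record_difficulty_rating(s, 11), "between 1 and 10")
  record_difficulty_rating(s, 10)
  expect_true(all(session_log(s)$difficulty_rating == 10L))
  record_difficulty_rating(s, 1)
  expect_true(all(session_log(s)$difficulty_rating == 1L))

  # rating survives the CSV round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_log(session_log(s), path)
  back <- read_session_log(path)
  expect_equal(back$difficulty_rating, session_log(s)$difficulty_rating)
  expect_equal(names(back), names(session_log(s)))
})

test_that("replaying a log's correct moves reproduces the trial boards", {
  tr <- trial_bank()[[2]]
  log <- simulate_cohort(player_model(p_false = 0.5, p_hint = 0.2), tr,
                         seed = 31)
  correct <- log[log$accuracy == "correct", ]
  b <- tr$initial_board
  for (i in seq_len(nrow(correct))) {
    mv <- unlist(correct[i, c("r1", "c1", "r2", "c2")], use.names = FALSE)
    # the logged correct move is the unique valid move of the board
    om <- oracle_valid_moves(b)
    expect_equal(unlist(om[1, ], use.names = FALSE), mv)
    if (i < nrow(correct)) {
      b <- resolve_match(apply_swap(b, mv), tr$matches[[i]]$refill)
    }
  }
})

test_that("level-order shuffling is seed-deterministic", {
  lv <- enumerate_level_specs()[1:10, ]
  a <- randomize_level_order(lv, seed = 12)
  b <- randomize_level_order(lv, seed = 12)
  expect_identical(a, b)
  expect_setequal(a$level_id, lv$level_id)
  expect_false(identical(a$level_id, lv$level_id))
})
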