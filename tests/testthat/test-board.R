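# Core board mechanics: run detection, swap legality, match resolution.

test_that("find_runs matches an exhaustive row/column scan", {
  # uniform board: every row and column is one maximal run
  uni <- smt_board(matrix(0L, 4, 4), t = 4)
  runs <- find_runs(uni)
  expect_equal(nrow(runs), 8L)
  expect_true(all(runs$length == 4L))
  expect_equal(sum(runs$orientation == "horizontal"), 4L)

  # the worked example board is stable
  expect_equal(nrow(find_runs(board_w())), 0L)
  expect_true(is_stable(board_w()))

  # after the unique swap there is exactly one horizontal run of tile 0
  after <- apply_swap(board_w(), c(4, 3, 4, 4))
  runs <- find_runs(after)
  expect_equal(nrow(runs), 1L)
  expect_equal(as.list(runs[1, ]),
               list(orientation = "horizontal", tile = 0L, row = 4L,
                    col = 1L, length = 3L))

  # random boards agree with the independent rle-scan oracle
  set.seed(11)
  for (i in 1:50) {
    m <- matrix(sample.int(3, 30, replace = TRUE) - 1L, 5, 6)
    got <- find_runs(smt_board(m, 3))
    want <- oracle_runs(m)
    want <- want[order(want$orientation, want$row, want$col), ]
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("board validation rejects malformed input", {
  expect_error(smt_board(matrix(0:3, 2, 2), t = 3), "tile ids")
  expect_error(smt_board("no", t = 4), "matrix")
  expect_error(board_from_lines(c("0 1 2", "0 1"), 4), "ragged")
})

test_that("apply_swap is an involution and rejects bad moves", {
  set.seed(21)
  for (i in 1:25) {
    m <- matrix(sample.int(4, 20, replace = TRUE) - 1L, 4, 5)
    b <- smt_board(m, 4)
    r <- sample.int(4, 1)
    cc <- sample.int(4, 1)
    mv <- c(r, cc, r, cc + 1L)
    expect_identical(board_matrix(apply_swap(apply_swap(b, mv), mv)),
                     board_matrix(b))
  }
  b <- board_w()
  expect_equal(board_matrix(apply_swap(b, c(4, 3, 4, 4)))[4, ],
               c(0L, 0L, 0L, 1L))
  expect_error(apply_swap(b, c(1, 1, 3, 1)), "adjacent")
  expect_error(apply_swap(b, c(1, 1, 2, 2)), "adjacent")
  expect_error(apply_swap(b, c(0, 1, 1, 1)), "bounds")
  expect_error(apply_swap(b, c(4, 4, 4, 5)), "bounds")
})

test_that("resolve_match removes runs, applies gravity and refill", {
  after <- apply_swap(board_w(), c(4, 3, 4, 4))
  refill <- list(3L, 2L, 0L, integer(0))
  got <- resolve_match(after, refill)
  # derived by hand: bottom-row run (tile 0, cols 1:3) is removed, each
  # of those columns drops one row and takes its refill tile on top;
  # column 4 is untouched and keeps the swapped-in 1 at the bottom
  expect_equal(board_matrix(got),
               matrix(c(3, 2, 0, 3,
                        0, 1, 2, 0,
                        1, 2, 3, 1,
                        2, 3, 1, 1), 4, 4, byrow = TRUE))
  # conservation: full board, same dimensions
  expect_equal(dim(board_matrix(got)), c(4L, 4L))
  expect_false(anyNA(board_matrix(got)))

  expect_error(resolve_match(after, list(3L, 2L, integer(0), integer(0))),
               "refill stream for column 3")
  expect_error(resolve_match(after, list(3L, 2L, 9L, integer(0))),
               "invalid tile ids")
  expect_error(resolve_match(board_w(), refill), "no runs")
})

test_that("resolve_match conserves cells on random unstable boards", {
  set.seed(33)
  n_checked <- 0L
  while (n_checked < 20L) {
    m <- matrix(sample.int(3, 36, replace = TRUE) - 1L, 6, 6)
    if (!oracle_has_run(m)) next
    n_checked <- n_checked + 1L
    # per-column demand derived with the independent oracle
    runs <- oracle_runs(m)
    removed <- matrix(FALSE, 6, 6)
    for (i in seq_len(nrow(runs))) {
      if (runs$orientation[i] == "horizontal") {
        removed[runs$row[i], runs$col[i] + 0:(runs$length[i] - 1)] <- TRUE
      } else {
        removed[runs$row[i] + 0:(runs$length[i] - 1), runs$col[i]] <- TRUE
      }
    }
    need <- colSums(removed)
    refill <- lapply(need, function(n) {
      if (n == 0) integer(0) else sample.int(3, n, replace = TRUE) - 1L
    })
    out <- resolve_match(smt_board(m, 3), refill)
    expect_equal(dim(board_matrix(out)), c(6L, 6L))
    # surviving tiles preserve their column order under gravity
    for (cc in 1:6) {
      survivors <- m[!removed[, cc], cc]
      expect_equal(tail(board_matrix(out)[, cc], length(survivors)),
                   survivors)
      expect_equal(head(board_matrix(out)[, cc], need[cc]),
                   as.integer(refill[[cc]]))
    }
  }
})

test_that("enumerate_valid_moves equals the exhaustive swap oracle", {
  # worked example: exactly one move
  got <- enumerate_valid_moves(board_w())
  expect_equal(nrow(got), 1L)
  expect_equal(unlist(got[1, ], use.names = FALSE), c(4L, 3L, 4L, 4L))
  expect_equal(move_keys(got), move_keys(oracle_valid_moves(board_w())))

  # Latin-square board: whatever the oracle says is ground truth
  expect_equal(move_keys(enumerate_valid_moves(latin_board())),
               move_keys(oracle_valid_moves(latin_board())))

  # property: agreement on random stable boards across level specs
  set.seed(42)
  for (lvl in list(c(4, 4, 4), c(5, 5, 5), c(6, 6, 6))) {
    for (i in 1:1000) {
      b <- random_stable_board(lvl)
      expect_equal(move_keys(enumerate_valid_moves(b)),
                   move_keys(oracle_valid_moves(b)))
    }
  }
})

test_that("identical-tile swaps are never valid moves", {
  set.seed(5)
  for (i in 1:100) {
    b <- random_stable_board(c(5, 5, 4))
    mv <- enumerate_valid_moves(b)
    m <- board_matrix(b)
    if (nrow(mv) == 0L) next
    tiles_a <- m[cbind(mv$r1, mv$c1)]
    tiles_b <- m[cbind(mv$r2, mv$c2)]
    expect_true(all(tiles_a != tiles_b))
  }
})

test_that("move enumeration raises exactly when the board is unstable", {
  set.seed(6)
  for (i in 1:60) {
    m <- matrix(sample.int(3, 25, replace = TRUE) - 1L, 5, 5)
    b <- smt_board(m, 3)
    if (nrow(find_runs(b)) > 0L) {
      expect_error(enumerate_valid_moves(b), "stable")
      expect_error(count_target_moves(b), "stable")
    } else {
      expect_no_error(enumerate_valid_moves(b))
    }
  }
})

test_that("board text serialization round-trips", {
  b <- board_w()
  expect_identical(board_matrix(board_from_lines(board_to_lines(b), 4)),
                   board_matrix(b))
})
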