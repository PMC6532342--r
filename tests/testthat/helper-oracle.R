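# Shared fixtures and independent oracles.
#
# The oracles here deliberately re-derive board facts from first
# principles (plain rle scans over rows and columns, exhaustive swap
# trial) without touching the package's internal fast paths, so they can
# stand as ground truth against the implementation.

# The worked 4x4 example board: stable, with exactly one valid move
# (4,3)<->(4,4) completing a horizontal run of tile 0 in the bottom row.
board_w <- function() {
  smt_board(matrix(c(0, 1, 2, 3,
                     1, 2, 3, 0,
                     2, 3, 1, 1,
                     0, 0, 1, 0), 4, 4, byrow = TRUE), t = 4)
}

latin_board <- function() {
  smt_board(matrix(c(0, 1, 2, 3,
                     1, 2, 3, 0,
                     2, 3, 0, 1,
                     3, 0, 1, 2), 4, 4, byrow = TRUE), t = 4)
}

# ---- independent oracles ----------------------------------------------------

oracle_runs <- function(m) {
  out <- list()
  for (r in seq_len(nrow(m))) {
    rl <- rle(m[r, ])
    start <- cumsum(rl$lengths) - rl$lengths + 1L
    for (i in which(rl$lengths >= 3L)) {
      out[[length(out) + 1L]] <- data.frame(
        orientation = "horizontal", tile = rl$values[i], row = r,
        col = start[i], length = rl$lengths[i])
    }
  }
  for (cc in seq_len(ncol(m))) {
    rl <- rle(m[, cc])
    start <- cumsum(rl$lengths) - rl$lengths + 1L
    for (i in which(rl$lengths >= 3L)) {
      out[[length(out) + 1L]] <- data.frame(
        orientation = "vertical", tile = rl$values[i], row = start[i],
        col = cc, length = rl$lengths[i])
    }
  }
  if (length(out) == 0L) {
    data.frame(orientation = character(0), tile = integer(0),
               row = integer(0), col = integer(0), length = integer(0))
  } else {
    do.call(rbind, out)
  }
}

oracle_has_run <- function(m) nrow(oracle_runs(m)) > 0L

# Exhaustive swap oracle: try every adjacent pair, rescan the whole
# board. Returns a data frame of canonical moves.
oracle_valid_moves <- function(board) {
  m <- if (inherits(board, "smt_board")) board_matrix(board) else board
  h <- nrow(m)
  w <- ncol(m)
  moves <- list()
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      for (d in list(c(0L, 1L), c(1L, 0L))) {
        r2 <- r + d[1]
        c2 <- cc + d[2]
        if (r2 > h || c2 > w) next
        m2 <- m
        m2[r, cc] <- m[r2, c2]
        m2[r2, c2] <- m[r, cc]
        if (oracle_has_run(m2)) {
          moves[[length(moves) + 1L]] <- data.frame(r1 = r, c1 = cc,
                                                    r2 = r2, c2 = c2)
        }
      }
    }
  }
  if (length(moves) == 0L) {
    data.frame(r1 = integer(0), c1 = integer(0), r2 = integer(0),
               c2 = integer(0))
  } else {
    do.call(rbind, moves)
  }
}

# Same move set as two sorted key vectors, for set comparison.
move_keys <- function(df) {
  sort(sprintf("%d,%d,%d,%d", df$r1, df$c1, df$r2, df$c2))
}

# Embed a 3-cell offset configuration (tile id 1) into a run-free
# checkerboard background (ids 2/3) with a one-cell margin, so isolated
# pattern properties can be probed with real board mechanics.
embed_pattern <- function(offsets, t = 4L) {
  hh <- max(offsets[, 1]) + 3L
  ww <- max(offsets[, 2]) + 3L
  bg <- outer(seq_len(hh), seq_len(ww), function(r, c) (r + c) %% 2L + 2L)
  for (k in seq_len(nrow(offsets))) {
    bg[offsets[k, 1] + 2L, offsets[k, 2] + 2L] <- 1L
  }
  smt_board(bg, t)
}

# A small bank of validated trials, generated once per test run.
trial_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) {
      levels <- list(c(4, 4, 4), c(5, 5, 5), c(6, 6, 6), c(4, 5, 4),
                     c(6, 6, 4), c(5, 5, 4))
      bank <<- lapply(seq_along(levels), function(i) {
        generate_trial(levels[[i]], seed = 1000L + i)
      })
    }
    bank
  }
})
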