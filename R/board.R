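#' Create a match-3 puzzle board
#'
#' A board is a dense `h` x `w` grid of tile identifiers. Tile ids are
#' integers in `0:(t - 1)`; how ids map onto colored polygons is cosmetic
#' and outside the scope of this package. Rows are counted from the top
#' (row 1 is the top row), so gravity moves tiles toward larger row
#' indices and refill tiles enter at row 1.
#'
#' @param tiles Integer matrix (rows = board height, columns = width) of
#'   tile ids in `0:(t - 1)`.
#' @param t Number of distinct tile types the board draws from.
#' @return An object of class `smt_board`: the tile matrix with a `t`
#'   attribute.
#' @examples
#' b <- smt_board(matrix(c(0, 1, 2, 3,
#'                         1, 2, 3, 0,
#'                         2, 3, 1, 1,
#'                         0, 0, 1, 0), 4, 4, byrow = TRUE), t = 4)
#' find_runs(b)
#' enumerate_valid_moves(b)
#' @export
smt_board <- function(tiles, t) {
  if (is.data.frame(tiles)) tiles <- as.matrix(tiles)
  if (!is.matrix(tiles) || !is.numeric(tiles)) {
    stop("`tiles` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(tiles) <- "integer"
  if (anyNA(tiles)) stop("board contains missing tiles", call. = FALSE)
  t <- as_count(t, "t", min = 2L)
  if (any(tiles < 0L) || any(tiles >= t)) {
    stop(sprintf("tile ids must lie in 0:%d", t - 1L), call. = FALSE)
  }
  structure(tiles, t = t, class = "smt_board")
}

#' @export
print.smt_board <- function(x, ...) {
  cat(sprintf("<smt_board %dx%d, %d tile types>\n",
              ncol(x), nrow(x), board_types(x)))
  m <- board_matrix(x)
  for (r in seq_len(nrow(m))) cat(" ", paste(m[r, ], collapse = " "), "\n")
  invisible(x)
}

#' Board dimensions and tile alphabet
#'
#' @param board An [smt_board()].
#' @return `board_width()`/`board_height()` return the number of columns
#'   and rows; `board_types()` the number of tile types `t`;
#'   `board_matrix()` the bare integer tile matrix.
#' @export
board_width <- function(board) ncol(assert_board(board))

#' @rdname board_width
#' @export
board_height <- function(board) nrow(assert_board(board))

#' @rdname board_width
#' @export
board_types <- function(board) attr(assert_board(board), "t", exact = TRUE)

#' @rdname board_width
#' @export
board_matrix <- function(board) {
  m <- unclass(assert_board(board))
  attributes(m) <- list(dim = dim(m))
  m
}

assert_board <- function(board) {
  if (!inherits(board, "smt_board")) {
    stop("expected an `smt_board` object", call. = FALSE)
  }
  board
}

# ---- fast internal primitives on bare matrices ------------------------------
# The inner loops (run scan, swap enumeration) live in src/mechanics.cpp;
# these wrappers keep the rest of the package in plain R.

# Any horizontal or vertical run of >= 3 equal tiles?
has_run_mat <- function(m) {
  cpp_has_run(m)
}

# All valid moves on a stable matrix, stopping once `cap` moves are found.
# Returns an n x 4 matrix of canonical moves (r1, c1, r2, c2).
valid_moves_mat <- function(m, cap = Inf) {
  cap <- if (is.finite(cap)) as.integer(cap) else 4L * length(m)
  mm <- cpp_valid_moves(m, cap)
  colnames(mm) <- c("r1", "c1", "r2", "c2")
  mm
}

# Maximal runs on a matrix as a data frame (no board validation).
runs_mat <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  rows <- list()
  k <- 0L
  if (w >= 3L) {
    for (r in seq_len(h)) {
      rl <- rle(m[r, ])
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      hit <- which(rl$lengths >= 3L)
      for (i in hit) {
        k <- k + 1L
        rows[[k]] <- list(orientation = "horizontal", tile = rl$values[i],
                          row = r, col = starts[i], length = rl$lengths[i])
      }
    }
  }
  if (h >= 3L) {
    for (cc in seq_len(w)) {
      rl <- rle(m[, cc])
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      hit <- which(rl$lengths >= 3L)
      for (i in hit) {
        k <- k + 1L
        rows[[k]] <- list(orientation = "vertical", tile = rl$values[i],
                          row = starts[i], col = cc, length = rl$lengths[i])
      }
    }
  }
  if (k == 0L) {
    tibble(orientation = character(0), tile = integer(0), row = integer(0),
           col = integer(0), length = integer(0))
  } else {
    dplyr::bind_rows(lapply(rows, as_tibble))
  }
}

# ---- public operations ------------------------------------------------------

#' Find all maximal runs on a board
#'
#' A run is a maximal horizontal or vertical sequence of three or more
#' identical tiles. A board with no runs is *stable*: nothing would
#' auto-eliminate.
#'
#' @param board An [smt_board()].
#' @return A tibble with one row per run: `orientation`
#'   (`"horizontal"`/`"vertical"`), `tile`, `row` and `col` of the run's
#'   first (top/left) cell, and `length`. Zero rows iff the board is
#'   stable.
#' @seealso [is_stable()], [resolve_match()]
#' @export
find_runs <- function(board) {
  m <- board_matrix(board)
  out <- runs_mat(m)
  dplyr::arrange(out, .data$orientation, .data$row, .data$col)
}

#' @rdname find_runs
#' @export
is_stable <- function(board) {
  !has_run_mat(board_matrix(board))
}

#' Enumerate all valid moves on a stable board
#'
#' A move swaps two orthogonally adjacent tiles; it is valid exactly when
#' the swap creates at least one run of three. Swapping two identical
#' tiles never changes the board and is therefore never valid. Moves are
#' returned in canonical unordered form (smaller cell first), so each
#' swap appears once.
#'
#' @param board A stable [smt_board()].
#' @return A tibble with columns `r1`, `c1`, `r2`, `c2`, one row per valid
#'   move, in row-major scan order.
#' @export
enumerate_valid_moves <- function(board) {
  m <- board_matrix(board)
  if (has_run_mat(m)) {
    stop("board is not stable: it already contains a run", call. = FALSE)
  }
  as_tibble(valid_moves_mat(m))
}

#' Swap two adjacent tiles
#'
#' Returns a new board with the tiles of the two cells exchanged; the
#' input board is not modified. Applying the same move twice restores the
#' original board.
#'
#' @param board An [smt_board()].
#' @param move Integer vector `c(r1, c1, r2, c2)` naming two orthogonally
#'   adjacent in-bounds cells.
#' @return The swapped [smt_board()].
#' @export
apply_swap <- function(board, move) {
  m <- board_matrix(board)
  move <- canonical_move(move)
  if (any(move[c(1, 3)] < 1L) || any(move[c(1, 3)] > nrow(m)) ||
      any(move[c(2, 4)] < 1L) || any(move[c(2, 4)] > ncol(m))) {
    stop("move cells out of bounds", call. = FALSE)
  }
  if (!is_adjacent_move(move)) {
    stop("move cells must be orthogonally adjacent", call. = FALSE)
  }
  tmp <- m[move[1], move[2]]
  m[move[1], move[2]] <- m[move[3], move[4]]
  m[move[3], move[4]] <- tmp
  smt_board(m, board_types(board))
}

# Removal mask for all current runs; per-column removal counts.
removal_mask_mat <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  rm <- matrix(FALSE, h, w)
  runs <- runs_mat(m)
  for (i in seq_len(nrow(runs))) {
    if (runs$orientation[i] == "horizontal") {
      rm[runs$row[i], runs$col[i] + 0:(runs$length[i] - 1L)] <- TRUE
    } else {
      rm[runs$row[i] + 0:(runs$length[i] - 1L), runs$col[i]] <- TRUE
    }
  }
  rm
}

# Drop removed cells, let survivors fall, leave NA holes at the top.
collapse_mat <- function(m, rm) {
  h <- nrow(m)
  for (cc in seq_len(ncol(m))) {
    keep <- m[!rm[, cc], cc]
    m[, cc] <- c(rep(NA_integer_, h - length(keep)), keep)
  }
  m
}

#' Resolve all matches on a board
#'
#' Removes every cell that belongs to a run, lets the surviving tiles in
#' each column fall downward (order preserved), and fills the empty cells
#' at the top of each column from that column's refill stream. The first
#' stream element ends up highest. The result has the same dimensions and
#' is completely filled; it may itself contain new runs (the trial
#' generator, not this operation, forbids that).
#'
#' @param board An [smt_board()] containing at least one run.
#' @param refill A list of `w` integer vectors of tile ids; element `c`
#'   must have exactly as many tiles as column `c` loses.
#' @return The resolved [smt_board()].
#' @export
resolve_match <- function(board, refill) {
  m <- board_matrix(board)
  t <- board_types(board)
  if (!has_run_mat(m)) {
    stop("board has no runs to resolve", call. = FALSE)
  }
  w <- ncol(m)
  if (!is.list(refill) || length(refill) != w) {
    stop(sprintf("`refill` must be a list of %d column streams", w),
         call. = FALSE)
  }
  rm <- removal_mask_mat(m)
  need <- colSums(rm)
  for (cc in seq_len(w)) {
    stream <- as.integer(refill[[cc]])
    if (length(stream) != need[cc]) {
      stop(sprintf("refill stream for column %d has %d tiles, needs %d",
                   cc, length(stream), need[cc]), call. = FALSE)
    }
    if (length(stream) > 0 && (anyNA(stream) || any(stream < 0L) ||
                               any(stream >= t))) {
      stop(sprintf("refill stream for column %d holds invalid tile ids", cc),
           call. = FALSE)
    }
  }
  m <- collapse_mat(m, rm)
  for (cc in seq_len(w)) {
    if (need[cc] > 0L) m[seq_len(need[cc]), cc] <- as.integer(refill[[cc]])
  }
  smt_board(m, t)
}

#' Serialize / deserialize a board as text lines
#'
#' The canonical text form is `h` lines of `w` space-separated tile ids,
#' top row first. Used inside trial files.
#'
#' @param board An [smt_board()].
#' @return `board_to_lines()` a character vector of `h` lines;
#'   `board_from_lines()` an [smt_board()].
#' @export
board_to_lines <- function(board) {
  m <- board_matrix(board)
  vapply(seq_len(nrow(m)), function(r) paste(m[r, ], collapse = " "), "")
}

#' @rdname board_to_lines
#' @param lines Character vector of `h` lines of `w` space-separated ids.
#' @param t Number of tile types.
#' @export
board_from_lines <- function(lines, t) {
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.integer)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged board: rows have different widths", call. = FALSE)
  }
  smt_board(do.call(rbind, rows), t)
}

#' Plot a board as a tile grid
#'
#' Diagnostic rendering: one colored square per cell, labelled with its
#' tile id. Not a reproduction of any particular game front end.
#'
#' @param object An [smt_board()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smt_board <- function(object, ...) {
  m <- board_matrix(object)
  df <- tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    tile = factor(as.vector(m), levels = 0:(board_types(object) - 1L))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$tile)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$tile), size = 3) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(m))) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(m)),
                                position = "top") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
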