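# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed when one is supplied, leaving the
# caller's RNG state untouched; otherwise use the current RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Integer scalar coercion with a readable error.
as_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer", name), call. = FALSE)
  }
  x <- as.integer(x)
  if (x < min) {
    stop(sprintf("`%s` must be >= %d", name, min), call. = FALSE)
  }
  x
}

# Canonical form of a move: the lexicographically smaller (row, col) cell
# first, so (a, b) and (b, a) denote the same move.
canonical_move <- function(move) {
  move <- as.integer(move)
  if (length(move) != 4L || anyNA(move)) {
    stop("a move is four integers: r1, c1, r2, c2", call. = FALSE)
  }
  a <- move[1:2]
  b <- move[3:4]
  if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) {
    move <- c(b, a)
  }
  move
}

move_key <- function(move) {
  paste(canonical_move(move), collapse = ",")
}

# TRUE when the two cells of a canonical move are orthogonally adjacent.
is_adjacent_move <- function(move) {
  dr <- abs(move[1] - move[3])
  dc <- abs(move[2] - move[4])
  (dr + dc) == 1L
}
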