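# Plain-text trial files.
#
# Trials are pregenerated and stored as self-describing text files, one
# trial per file: a header (format version, level, trial id, seed), the
# initial board as h lines of w space-separated tile ids, and 4 match
# blocks each holding the solution move ("move r1 c1 r2 c2", 1-based
# row/col) and one refill line per column ("refill c: id id ...",
# possibly empty). LF line endings, UTF-8. The serialization is
# canonical: identical trials produce identical bytes, which enables
# hash-based regression tests.

TRIAL_FORMAT <- "smt-trial v1"

#' Write a trial to a text file
#'
#' Refuses to write a trial that fails [validate_trial()]. The output is
#' the canonical serialization: writing the same trial twice yields
#' byte-identical files.
#'
#' @param trial An `smt_trial` from [generate_trial()] or [read_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  report <- validate_trial(trial)
  if (!report$ok) {
    stop("refusing to write invalid trial: ",
         report$violations$message[1], call. = FALSE)
  }
  lines <- c(
    TRIAL_FORMAT,
    sprintf("level %d %d %d", trial$level$w, trial$level$h, trial$level$t),
    sprintf("trial_id %s", trial$trial_id),
    sprintf("seed %d", trial$seed),
    "board",
    board_to_lines(trial$initial_board)
  )
  for (i in seq_along(trial$matches)) {
    mt <- trial$matches[[i]]
    lines <- c(lines, sprintf("match %d", i),
               sprintf("move %s", paste(mt$move, collapse = " ")))
    for (cc in seq_along(mt$refill)) {
      ids <- mt$refill[[cc]]
      lines <- c(lines, sprintf("refill %d:%s", cc,
                                if (length(ids)) paste0(" ",
                                  paste(ids, collapse = " ")) else ""))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

parse_error <- function(lineno, msg) {
  stop(sprintf("trial file parse error at line %d: %s", lineno, msg),
       call. = FALSE)
}

#' Read a trial from a text file
#'
#' Parses the canonical trial format and re-checks structural invariants
#' (dimensions, tile id range, 4 match blocks, one refill line per
#' column). Parse errors name the offending line. Replay-level validity
#' (stability, unique move, refill reproduction) is checked separately
#' by [validate_trial()].
#'
#' @param path Path to a trial file.
#' @return An `smt_trial`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n < 1L || lines[1] != TRIAL_FORMAT) {
    parse_error(1L, sprintf("expected header '%s'", TRIAL_FORMAT))
  }
  lv <- strsplit(lines[2], "\\s+")[[1]]
  if (length(lv) != 4L || lv[1] != "level" || anyNA(as.integer(lv[2:4]))) {
    parse_error(2L, "expected 'level w h t'")
  }
  w <- as.integer(lv[2]); h <- as.integer(lv[3]); t <- as.integer(lv[4])
  if (!startsWith(lines[3], "trial_id ")) parse_error(3L, "expected trial_id")
  trial_id <- sub("^trial_id ", "", lines[3])
  if (!startsWith(lines[4], "seed ")) parse_error(4L, "expected seed")
  seed <- suppressWarnings(as.integer(sub("^seed ", "", lines[4])))
  if (is.na(seed)) parse_error(4L, "seed must be an integer")
  if (lines[5] != "board") parse_error(5L, "expected 'board'")
  if (n < 5L + h) parse_error(n, "board block truncated")
  board <- tryCatch(
    board_from_lines(lines[6:(5L + h)], t),
    error = function(e) parse_error(6L, conditionMessage(e))
  )
  if (ncol(board) != w || nrow(board) != h) {
    parse_error(6L, sprintf("board is %dx%d, header says %dx%d",
                            ncol(board), nrow(board), w, h))
  }
  pos <- 6L + h
  matches <- list()
  while (pos <= n && nzchar(lines[pos])) {
    i <- length(matches) + 1L
    if (lines[pos] != sprintf("match %d", i)) {
      parse_error(pos, sprintf("expected 'match %d'", i))
    }
    pos <- pos + 1L
    mv <- strsplit(lines[pos], "\\s+")[[1]]
    if (length(mv) != 5L || mv[1] != "move" || anyNA(as.integer(mv[2:5]))) {
      parse_error(pos, "expected 'move r1 c1 r2 c2'")
    }
    move <- canonical_move(as.integer(mv[2:5]))
    pos <- pos + 1L
    refill <- vector("list", w)
    for (cc in seq_len(w)) {
      if (pos > n) parse_error(n, sprintf("missing refill line for column %d",
                                          cc))
      prefix <- sprintf("refill %d:", cc)
      if (!startsWith(lines[pos], prefix)) {
        parse_error(pos, sprintf("expected '%s'", prefix))
      }
      payload <- trimws(substring(lines[pos], nchar(prefix) + 1L))
      ids <- if (nzchar(payload)) {
        v <- suppressWarnings(as.integer(strsplit(payload, "\\s+")[[1]]))
        if (anyNA(v)) parse_error(pos,
                                  sprintf("bad tile id in refill column %d",
                                          cc))
        v
      } else integer(0)
      if (length(ids) && (any(ids < 0L) || any(ids >= t))) {
        parse_error(pos, sprintf("tile id out of range in refill column %d",
                                 cc))
      }
      refill[[cc]] <- ids
      pos <- pos + 1L
    }
    matches[[i]] <- list(move = move, refill = refill)
  }
  if (length(matches) != 4L) {
    parse_error(min(pos, n),
                sprintf("expected 4 match blocks, found %d",
                        length(matches)))
  }
  new_trial(as_level(c(w, h, t)), board, matches, seed, trial_id = trial_id)
}

#' Validate a trial by independent replay
#'
#' Replays the trial using only the core board mechanics and the
#' brute-force swap enumeration (no template code): each of the four
#' boards must be stable and contain exactly one valid move; that move
#' must match the stored solution and (by default) create exactly one
#' run of exactly three; each refill must have the right per-column
#' length so resolution reproduces the next board.
#'
#' @param trial An `smt_trial`.
#' @param forbid_runs_gt3 Also require the single-run-of-3 property
#'   (default `TRUE`, the generator's contract).
#' @return A list of class `smt_validation`: `ok` (logical),
#'   `violations` (tibble `board_index`, `check`, `message`; zero rows
#'   when valid) and `boards` (the replayed boards up to the first
#'   violation).
#' @export
validate_trial <- function(trial, forbid_runs_gt3 = TRUE) {
  violations <- list()
  boards <- list()
  fail <- function(i, check, msg) {
    violations[[length(violations) + 1L]] <<-
      tibble(board_index = i, check = check, message = msg)
  }
  ok_structure <- is.list(trial) && inherits(trial, "smt_trial") &&
    length(trial$matches) == 4L && inherits(trial$initial_board, "smt_board")
  if (!ok_structure) {
    fail(NA_integer_, "structure", "expected an smt_trial with 4 match blocks")
  } else {
    b <- trial$initial_board
    w <- trial$level$w
    for (i in 1:4) {
      boards[[i]] <- b
      m <- board_matrix(b)
      if (has_run_mat(m)) {
        fail(i, "stability", sprintf("board %d is unstable", i))
        break
      }
      mv <- valid_moves_mat(m, cap = 3L)
      if (nrow(mv) != 1L) {
        fail(i, "single_target",
             sprintf("board %d: %d valid moves", i, nrow(mv)))
        break
      }
      stored <- canonical_move(trial$matches[[i]]$move)
      if (!all(as.integer(mv[1, ]) == stored)) {
        fail(i, "solution",
             sprintf("board %d: stored solution is not the valid move", i))
        break
      }
      if (forbid_runs_gt3) {
        after <- apply_swap(b, stored)
        runs <- find_runs(after)
        if (nrow(runs) != 1L || runs$length[1] != 3L) {
          fail(i, "single_match",
               sprintf("board %d: move does not create exactly one run of 3",
                       i))
          break
        }
      }
      refill <- trial$matches[[i]]$refill
      if (!is.list(refill) || length(refill) != w) {
        fail(i, "refill", sprintf("board %d: refill must list %d columns",
                                  i, w))
        break
      }
      nxt <- tryCatch(
        resolve_match(apply_swap(b, stored), refill),
        error = function(e) e
      )
      if (inherits(nxt, "error")) {
        fail(i, "refill", sprintf("board %d: %s", i, conditionMessage(nxt)))
        break
      }
      if (i < 4L) b <- nxt
    }
  }
  violations <- if (length(violations)) dplyr::bind_rows(violations) else
    tibble(board_index = integer(0), check = character(0),
           message = character(0))
  structure(list(ok = nrow(violations) == 0L, violations = violations,
                 boards = boards),
            class = "smt_validation")
}

#' @export
print.smt_validation <- function(x, ...) {
  if (x$ok) {
    cat("<smt_validation> PASS\n")
  } else {
    cat("<smt_validation> FAIL:", x$violations$message[1], "\n")
  }
  invisible(x)
}
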