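# Target and distractor pattern taxonomy.
#
# A target pattern is a configuration of 3 identical tiles from which
# exactly one swap of two orthogonally adjacent cells produces a
# horizontal or vertical line of three. In isolation ("alone on an empty
# board region") a swap amounts to moving one of the three tiles onto an
# adjacent free cell. Enumerating every 3-cell configuration in a small
# window under that rule recovers the classic taxonomy: 16 templates in
# three families (J: move diagonal from a pair, V: move between two
# identical tiles, i: move toward a pair).

.smt_cache <- new.env(parent = emptyenv())

# cells: n x 2 integer matrix of (row, col) offsets
normalize_offsets <- function(cells) {
  cells[, 1] <- cells[, 1] - min(cells[, 1])
  cells[, 2] <- cells[, 2] - min(cells[, 2])
  cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
}

offsets_key <- function(cells) {
  paste(t(cells), collapse = ",")
}

# Is a 3-cell set a contiguous horizontal or vertical line?
is_line3 <- function(cells) {
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  (length(unique(cells[, 1])) == 1L &&
     all(diff(cells[, 2]) == 1L)) ||
    (length(unique(cells[, 2])) == 1L &&
       all(diff(cells[, 1]) == 1L))
}

# All single-tile moves (tile -> adjacent free cell) that turn the 3-cell
# configuration into a line of three. Returns a list of list(from, to).
completing_moves_config <- function(cells) {
  steps <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  found <- list()
  for (i in 1:3) {
    for (s in 1:4) {
      to <- cells[i, ] + steps[s, ]
      occupied <- any(cells[, 1] == to[1] & cells[, 2] == to[2])
      if (occupied) next
      cand <- cells
      cand[i, ] <- to
      if (is_line3(cand)) {
        found[[length(found) + 1L]] <- list(from = cells[i, ], to = to)
      }
    }
  }
  found
}

# Family of a template given its configuration and unique completing move.
template_family <- function(cells, move) {
  line <- cells
  line[which(cells[, 1] == move$from[1] & cells[, 2] == move$from[2]), ] <-
    move$to
  line <- line[order(line[, 1], line[, 2]), , drop = FALSE]
  horizontal <- length(unique(line[, 1])) == 1L
  mid <- line[2, ]
  if (all(move$to == mid)) return("V")
  along <- if (horizontal) move$from[1] == move$to[1] else
    move$from[2] == move$to[2]
  if (along) "i" else "J"
}

#' Enumerate the 3-tile target pattern templates
#'
#' Brute-force enumeration: every configuration of three cells in a small
#' window is tested for the defining property that exactly one adjacent
#' swap (moving one tile onto a neighboring free cell) yields a line of
#' three. Configurations are deduplicated up to translation only:
#' rotations and reflections count as distinct templates, which is the
#' counting convention under which there are 16 of them.
#'
#' @return A tibble with one row per template, in deterministic order
#'   (sorted by normalized offsets): `template_id`, `family` (`"J"`,
#'   `"V"` or `"i"`), `orientation` of the completed line, `offsets`
#'   (list column of 3 x 2 matrices of 0-based `(row, col)` offsets,
#'   normalized so the minimum row and column are 0), and the completing
#'   move as `from_r`, `from_c`, `to_r`, `to_c` in the same offset frame.
#' @seealso [classify_symmetry_families()], [count_target_moves()]
#' @export
enumerate_target_templates <- function() {
  if (!is.null(.smt_cache$templates)) return(.smt_cache$templates)
  win <- as.matrix(expand.grid(r = 0:3, c = 0:3))
  combos <- utils::combn(nrow(win), 3L)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (j in seq_len(ncol(combos))) {
    cells <- win[combos[, j], , drop = FALSE]
    moves <- completing_moves_config(cells)
    if (length(moves) != 1L) next
    shift <- c(min(cells[, 1]), min(cells[, 2]))
    norm <- normalize_offsets(cells)
    key <- offsets_key(norm)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    mv <- moves[[1]]
    from <- mv$from - shift
    to <- mv$to - shift
    line <- norm
    line[which(norm[, 1] == from[1] & norm[, 2] == from[2]), ] <- to
    orientation <- if (length(unique(line[, 1])) == 1L) "horizontal" else
      "vertical"
    rows[[length(rows) + 1L]] <- tibble(
      key = key,
      family = template_family(norm, list(from = from, to = to)),
      orientation = orientation,
      offsets = list(norm),
      from_r = from[1], from_c = from[2], to_r = to[1], to_c = to[2]
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$key)
  out <- dplyr::mutate(out, template_id = dplyr::row_number(),
                       .before = "key")
  out$key <- NULL
  .smt_cache$templates <- out
  out
}

# The 8 symmetries of the square applied to (row, col) offset matrices.
dihedral_images <- function(cells) {
  r <- cells[, 1]
  c <- cells[, 2]
  forms <- list(
    cbind(r, c), cbind(c, -r), cbind(-r, -c), cbind(-c, r),
    cbind(r, -c), cbind(-c, -r), cbind(-r, c), cbind(c, r)
  )
  lapply(forms, normalize_offsets)
}

#' Partition target templates into symmetry families
#'
#' Groups the target templates into equivalence classes (orbits) under
#' the eight symmetries of the square: four rotations times reflection.
#' The orbits coincide with the three basic families J, V and i.
#'
#' @param templates Output of [enumerate_target_templates()].
#' @return The input tibble with a `class_id` column; classes are
#'   numbered in order of first appearance. Attribute `n_classes` holds
#'   the number of orbits.
#' @export
classify_symmetry_families <- function(templates = enumerate_target_templates()) {
  orbit_key <- vapply(templates$offsets, function(cells) {
    min(vapply(dihedral_images(cells), offsets_key, ""))
  }, "")
  class_id <- as.integer(factor(orbit_key, levels = unique(orbit_key)))
  out <- dplyr::mutate(templates, class_id = class_id)
  attr(out, "n_classes") <- length(unique(class_id))
  out
}

#' Count target patterns on a board via template scan
#'
#' Slides every target template across the board; wherever the three
#' template cells hold identical tiles, the template's completing move is
#' a valid move on the board. The count of distinct canonical moves
#' equals `nrow(enumerate_valid_moves(board))`; the two routes (template
#' scan here, exhaustive swap enumeration there) are independent
#' implementations kept for cross-checking.
#'
#' @param board A stable [smt_board()].
#' @return Integer: the number of distinct valid moves (target patterns).
#' @export
count_target_moves <- function(board) {
  m <- board_matrix(board)
  if (has_run_mat(m)) {
    stop("board is not stable: it already contains a run", call. = FALSE)
  }
  h <- nrow(m)
  w <- ncol(m)
  templates <- enumerate_target_templates()
  keys <- character(0)
  for (i in seq_len(nrow(templates))) {
    off <- templates$offsets[[i]]
    mr <- max(off[, 1])
    mc <- max(off[, 2])
    if (mr + 1L > h || mc + 1L > w) next
    anchors <- expand.grid(ar = seq_len(h - mr), ac = seq_len(w - mc))
    idx <- function(k) {
      (anchors$ar + off[k, 1]) + (anchors$ac + off[k, 2] - 1L) * h
    }
    v1 <- m[idx(1)]
    hit <- v1 == m[idx(2)] & v1 == m[idx(3)]
    if (!any(hit)) next
    ar <- anchors$ar[hit]
    ac <- anchors$ac[hit]
    f_r <- ar + templates$from_r[i]
    f_c <- ac + templates$from_c[i]
    t_r <- ar + templates$to_r[i]
    t_c <- ac + templates$to_c[i]
    swap_first <- (f_r < t_r) | (f_r == t_r & f_c < t_c)
    k1 <- paste(f_r, f_c, t_r, t_c, sep = ",")
    k2 <- paste(t_r, t_c, f_r, f_c, sep = ",")
    keys <- c(keys, ifelse(swap_first, k1, k2))
  }
  length(unique(keys))
}

#' Enumerate distractor (false target) pattern templates
#'
#' Distractor patterns are near-miss configurations: two orthogonally
#' adjacent identical tiles plus a third identical tile displaced by one
#' cell from where a target pattern would have it, such that no adjacent
#' swap creates a line of three. The displacement rule is under-specified
#' in the source taxonomy, so this enumeration is a documented
#' best-effort: each target template's tiles are displaced by one
#' orthogonal step; candidates are kept when they contain an adjacent
#' pair, are not themselves a line or a target, and admit no completing
#' move. The resulting count is reported, not asserted against any
#' external figure.
#'
#' @return A tibble: `distractor_id`, `type_label` (`"A"` diagonal third
#'   tile, `"B"` collinear gapped third tile, `"C"` other), `derived_from`
#'   (families of the target templates that generate it), `offsets`
#'   (list column of normalized 3 x 2 offset matrices).
#' @export
enumerate_distractor_templates <- function() {
  if (!is.null(.smt_cache$distractors)) return(.smt_cache$distractors)
  targets <- enumerate_target_templates()
  steps <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  acc <- list()
  for (i in seq_len(nrow(targets))) {
    cells <- targets$offsets[[i]]
    for (k in 1:3) {
      for (s in 1:4) {
        cand <- cells
        cand[k, ] <- cand[k, ] + steps[s, ]
        if (any(duplicated(cand))) next
        cand <- normalize_offsets(cand)
        # adjacency among the three cells
        d <- as.matrix(stats::dist(cand, method = "manhattan"))
        if (!any(d[upper.tri(d)] == 1)) next
        if (is_line3(cand)) next
        if (length(completing_moves_config(cand)) != 0L) next
        acc[[length(acc) + 1L]] <- list(key = offsets_key(cand),
                                        cells = cand,
                                        family = targets$family[i])
      }
    }
  }
  keys <- vapply(acc, `[[`, "", "key")
  ord <- order(keys)
  acc <- acc[ord]
  keys <- keys[ord]
  uniq <- !duplicated(keys)
  rows <- list()
  for (j in which(uniq)) {
    fams <- sort(unique(vapply(acc[keys == keys[j]], `[[`, "", "family")))
    cand <- acc[[j]]$cells
    d <- as.matrix(stats::dist(cand, method = "manhattan"))
    pair <- which(d == 1 & upper.tri(d), arr.ind = TRUE)[1, ]
    third <- setdiff(1:3, pair)
    collinear <- length(unique(cand[, 1])) == 1L ||
      length(unique(cand[, 2])) == 1L
    cheb <- max(abs(cand[third, ] - cand[pair[1], ]),
                abs(cand[third, ] - cand[pair[2], ]))
    diag_third <- min(
      max(abs(cand[third, 1] - cand[pair[1], 1]),
          abs(cand[third, 2] - cand[pair[1], 2])),
      max(abs(cand[third, 1] - cand[pair[2], 1]),
          abs(cand[third, 2] - cand[pair[2], 2]))
    ) == 1L
    type <- if (collinear) "B" else if (diag_third) "A" else "C"
    rows[[length(rows) + 1L]] <- tibble(
      type_label = type,
      derived_from = paste(fams, collapse = ""),
      offsets = list(cand)
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, distractor_id = dplyr::row_number(),
                       .before = 1)
  .smt_cache$distractors <- out
  out
}

#' Export pattern templates as JSON
#'
#' Writes the target templates (offsets, completing move, family,
#' orientation) to a JSON document, e.g. for documentation or external
#' fixtures.
#'
#' @param path File path to write.
#' @param templates Output of [enumerate_target_templates()].
#' @return `path`, invisibly.
#' @export
templates_to_json <- function(path, templates = enumerate_target_templates()) {
  doc <- lapply(seq_len(nrow(templates)), function(i) {
    list(
      template_id = templates$template_id[i],
      family = templates$family[i],
      orientation = templates$orientation[i],
      offsets = unname(apply(templates$offsets[[i]], 1, as.list,
                             simplify = FALSE)),
      move = list(from = c(templates$from_r[i], templates$from_c[i]),
                  to = c(templates$to_r[i], templates$to_c[i]))
    )
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
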