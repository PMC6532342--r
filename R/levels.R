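# Factorial difficulty-level space.
#
# A difficulty level is a triple (w, h, t): board width, board height and
# number of tile types. Width and height each range over 4:8 (25 board
# sizes); for each size, t ranges from 4 up to max(w, h). Set size is
# w * h, the number of items that must be searched; t controls distractor
# heterogeneity.

#' Enumerate the factorial difficulty-level space
#'
#' All `(w, h, t)` combinations with `w, h` in `4:8` and
#' `4 <= t <= max(w, h)`: 25 board sizes and 95 levels in total. Levels
#' are sorted by `(set_size, w, h, t)`, the total order behind "sorted by
#' set size" used everywhere in the package.
#'
#' @param w_range,h_range Board widths and heights to cross (defaults
#'   `4:8`).
#' @param t_min Smallest number of tile types (default 4).
#' @return A tibble: `level_id`, `w`, `h`, `t`, `set_size`.
#' @examples
#' levels <- enumerate_level_specs()
#' nrow(levels)                       # 95
#' dplyr::n_distinct(levels$w, levels$h)  # 25
#' @export
enumerate_level_specs <- function(w_range = 4:8, h_range = 4:8, t_min = 4L) {
  grid <- expand.grid(w = as.integer(w_range), h = as.integer(h_range))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    w <- grid$w[i]
    h <- grid$h[i]
    tmax <- max(w, h)
    if (tmax < t_min) return(NULL)
    tibble(w = w, h = h, t = seq.int(t_min, tmax))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, set_size = .data$w * .data$h)
  out <- dplyr::arrange(out, .data$set_size, .data$w, .data$h, .data$t)
  out <- dplyr::mutate(out,
                       level_id = sprintf("w%d_h%d_t%d", .data$w, .data$h,
                                          .data$t),
                       .before = 1)
  out
}

#' Split feasible levels into two parallel versions
#'
#' Square levels (`w == h`) are duplicated into both versions so that
#' every available square set size appears in each. Rectangular levels
#' (`w != h`) are sorted by `(set_size, w, h, t)` and dealt out
#' alternately, first to version A. Both versions are returned sorted by
#' set size.
#'
#' @param levels A tibble with columns `w`, `h`, `t` (e.g. the feasible
#'   subset of [enumerate_level_specs()] or [survey_playability()]).
#' @return A named list of two tibbles, `A` and `B`.
#' @export
split_parallel_versions <- function(levels) {
  levels <- dplyr::mutate(levels, set_size = .data$w * .data$h)
  levels <- dplyr::arrange(levels, .data$set_size, .data$w, .data$h, .data$t)
  square <- dplyr::filter(levels, .data$w == .data$h)
  rect <- dplyr::filter(levels, .data$w != .data$h)
  to_a <- seq_len(nrow(rect)) %% 2L == 1L
  sort_version <- function(x) {
    dplyr::arrange(x, .data$set_size, .data$w, .data$h, .data$t)
  }
  list(
    A = sort_version(dplyr::bind_rows(square, rect[to_a, , drop = FALSE])),
    B = sort_version(dplyr::bind_rows(square, rect[!to_a, , drop = FALSE]))
  )
}

# Coerce a level argument: either a one-row tibble/list with w,h,t or a
# numeric vector c(w, h, t).
as_level <- function(level) {
  if (is.numeric(level) && length(level) == 3L) {
    level <- list(w = level[1], h = level[2], t = level[3])
  }
  w <- as_count(level$w, "w", min = 2L)
  h <- as_count(level$h, "h", min = 2L)
  t <- as_count(level$t, "t", min = 2L)
  list(w = w, h = h, t = t, set_size = w * h)
}
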