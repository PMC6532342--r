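# Time- and error-based performance indicators from move logs.
#
# The unit of analysis is the board: its search time is the sum of the
# elapsed times of all false moves leading up to (and including) the
# correct move. Boards on which a hint was used are excluded from the
# "without hints" statistics; outliers are filtered once with Tukey
# fences (1.5 x IQR beyond the quartiles) before hint exclusion.

#' Search time of one board
#'
#' Sums the elapsed times of every attempted move on a board: all false
#' moves leading up to the correct move, plus the correct move itself.
#'
#' @param entries Move-log rows of a single board (columns
#'   `elapsed_time`, `accuracy`).
#' @return Search time in seconds.
#' @export
board_search_time <- function(entries) {
  if (nrow(entries) == 0L || sum(entries$accuracy == "correct") != 1L) {
    stop("incomplete board: expected exactly one correct move",
         call. = FALSE)
  }
  if (any(!is.finite(entries$elapsed_time)) ||
      any(entries$elapsed_time <= 0)) {
    stop("elapsed times must be positive", call. = FALSE)
  }
  sum(entries$elapsed_time)
}

#' Per-board search times from a move log
#'
#' Collapses a move log to one row per played board, with its summed
#' search time, false-move count and hint flag.
#'
#' @param log A move-log tibble as produced by [session_log()] /
#'   [read_session_log()].
#' @return A tibble with one row per
#'   `(participant_id, trial_id, board_index)`: `group`, `w`, `h`, `t`,
#'   `set_size`, `search_time`, `n_false`, `hint_used`,
#'   `difficulty_rating`.
#' @export
board_search_times <- function(log) {
  if (nrow(log) == 0L) stop("empty move log", call. = FALSE)
  if (any(log$elapsed_time <= 0)) {
    stop("elapsed times must be positive", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(log, .data$participant_id, .data$group, .data$w,
                    .data$h, .data$t, .data$trial_id, .data$board_index),
    search_time = sum(.data$elapsed_time),
    n_false = sum(.data$accuracy == "false"),
    n_correct = sum(.data$accuracy == "correct"),
    hint_used = any(.data$hint_used),
    difficulty_rating = .data$difficulty_rating[1],
    .groups = "drop"
  )
  if (any(out$n_correct != 1L)) {
    stop("incomplete board(s): expected exactly one correct move per board",
         call. = FALSE)
  }
  out$n_correct <- NULL
  dplyr::mutate(out, set_size = .data$w * .data$h,
                .after = "t")
}

#' Tukey-fence outlier filter
#'
#' Within each group, drops observations outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by linear
#' interpolation between order statistics (`stats::quantile()` type 7).
#' The filter is applied once, not iterated. Groups with fewer than 4
#' observations are passed through untouched with a warning.
#'
#' @param data A data frame of per-board records, e.g. from
#'   [board_search_times()].
#' @param time_col Name of the column to filter on (default
#'   `"search_time"`).
#' @param group_cols Character vector of grouping columns (e.g. an age
#'   group label); `NULL` filters the whole table as one group.
#' @return The retained rows; attribute `n_removed` counts the dropped
#'   ones.
#' @export
filter_outliers <- function(data, time_col = "search_time",
                            group_cols = NULL) {
  keep_group <- function(x) {
    if (length(x) < 4L) {
      warning("group with fewer than 4 observations passed through unfiltered",
              call. = FALSE)
      return(rep(TRUE, length(x)))
    }
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr
  }
  if (is.null(group_cols)) {
    keep <- keep_group(data[[time_col]])
  } else {
    g <- interaction(data[group_cols], drop = TRUE)
    keep <- logical(nrow(data))
    for (lev in levels(g)) {
      idx <- which(g == lev)
      keep[idx] <- keep_group(data[[time_col]][idx])
    }
  }
  out <- data[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Processing time per item
#'
#' Search time divided by the number of items in the display (the set
#' size `w * h`).
#'
#' @param search_time Seconds (vectorized).
#' @param level A level (`c(w, h, t)` or anything with `$w`, `$h`), or
#'   supply `set_size` directly.
#' @param set_size Number of items; overrides `level`.
#' @return Seconds per item.
#' @export
processing_time_per_item <- function(search_time, level = NULL,
                                     set_size = NULL) {
  if (is.null(set_size)) {
    if (is.null(level)) stop("supply `level` or `set_size`", call. = FALSE)
    if (is.numeric(level) && length(level) >= 2L) {
      set_size <- level[1] * level[2]
    } else {
      set_size <- level$w * level$h
    }
  }
  if (any(search_time < 0)) stop("search times must be >= 0", call. = FALSE)
  search_time / set_size
}

#' Fit search slopes: search time as a function of set size
#'
#' The search slope (seconds per item of set size) indexes search
#' efficiency. The primary estimator is an ordinary least-squares
#' regression of per-board search time on set size, fitted per group.
#' Optionally a gamma-family GLM with inverse link and a set size x
#' group interaction is fitted as a cross-check, mirroring the model
#' conventionally used for positively skewed response times.
#'
#' @param data Per-board records with columns `search_time` and
#'   `set_size` (e.g. [board_search_times()] output).
#' @param group_col Optional name of a grouping column; one slope per
#'   group.
#' @param gamma_glm Also fit the gamma GLM (default `FALSE`).
#' @return An object of class `smt_slope_fit` with [tidy()], [glance()]
#'   and [autoplot()] methods. `tidy()` gives one row per group with the
#'   OLS `slope`, `intercept` and their standard errors.
#' @export
search_slope <- function(data, group_col = NULL, gamma_glm = FALSE) {
  if (dplyr::n_distinct(data$set_size) < 2L) {
    stop("search slope needs at least 2 distinct set sizes", call. = FALSE)
  }
  groups <- if (is.null(group_col)) {
    list(all = data)
  } else {
    split(data, data[[group_col]])
  }
  fits <- lapply(groups, function(d) lm(search_time ~ set_size, data = d))
  gamma_fit <- NULL
  if (gamma_glm) {
    gamma_fit <- if (is.null(group_col)) {
      glm(search_time ~ set_size, data = data,
          family = Gamma(link = "inverse"))
    } else {
      d <- data
      d$.group <- factor(d[[group_col]])
      glm(search_time ~ set_size * .group, data = d,
          family = Gamma(link = "inverse"))
    }
  }
  structure(list(fits = fits, gamma_fit = gamma_fit, data = data,
                 group_col = group_col),
            class = "smt_slope_fit")
}

#' @export
print.smt_slope_fit <- function(x, ...) {
  cat("<smt_slope_fit>\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname search_slope
#' @param x,object An `smt_slope_fit`.
#' @param ... Unused.
#' @export
tidy.smt_slope_fit <- function(x, ...) {
  rows <- lapply(names(x$fits), function(g) {
    sm <- summary(x$fits[[g]])$coefficients
    tibble(group = g,
           slope = sm["set_size", "Estimate"],
           slope_se = sm["set_size", "Std. Error"],
           intercept = sm["(Intercept)", "Estimate"],
           intercept_se = sm["(Intercept)", "Std. Error"])
  })
  dplyr::bind_rows(rows)
}

#' @rdname search_slope
#' @export
glance.smt_slope_fit <- function(x, ...) {
  rows <- lapply(names(x$fits), function(g) {
    sm <- summary(x$fits[[g]])
    tibble(group = g, r.squared = sm$r.squared, sigma = sm$sigma,
           nobs = length(sm$residuals))
  })
  dplyr::bind_rows(rows)
}

#' @rdname search_slope
#' @export
autoplot.smt_slope_fit <- function(object, ...) {
  d <- object$data
  d$group <- if (is.null(object$group_col)) "all" else
    as.character(d[[object$group_col]])
  means <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$set_size),
    search_time = mean(.data$search_time), .groups = "drop")
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$set_size, y = .data$search_time,
                               color = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(data = d, method = "lm", formula = y ~ x,
                         se = FALSE, linewidth = 0.6) +
    ggplot2::labs(x = "set size (items)", y = "search time (s)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Summarize a session log into performance indicators
#'
#' Computes, per participant, the time- and error-based indicators:
#' overall task completion time (minutes), average per-board search time
#' with and without hinted boards, geometric mean search time
#' (hint-free boards), mean processing time per item, the OLS search
#' slope when at least two set sizes were played, and false-move / hint
#' counts. Optionally applies the Tukey outlier filter to per-board
#' search times first (outlier filtering precedes hint exclusion). When
#' every board was hinted the without-hints statistics are `NA`
#' (missing, not zero).
#'
#' @param log A move-log tibble covering one or more participants.
#' @param remove_outliers Apply [filter_outliers()] to per-board search
#'   times before averaging (default `FALSE`).
#' @param outlier_group_cols Grouping for the outlier filter (default
#'   `"group"`, the age-group label).
#' @return A tibble with one row per participant:
#'   `participant_id`, `group`, `n_boards`, `task_completion_time_min`,
#'   `avg_search_time_with_hints`, `avg_search_time_without_hints`,
#'   `geometric_mean_search_time`, `processing_time_per_item`,
#'   `search_slope`, `n_false_moves`, `n_hints`, `n_excluded_outlier`.
#' @export
summarize_session <- function(log, remove_outliers = FALSE,
                              outlier_group_cols = "group") {
  boards <- board_search_times(log)
  completion <- dplyr::summarise(
    dplyr::group_by(log, .data$participant_id),
    task_completion_time_min = sum(.data$elapsed_time) / 60,
    .groups = "drop")
  n_removed_by <- NULL
  if (remove_outliers) {
    before <- dplyr::count(boards, .data$participant_id, name = "n_before")
    boards <- filter_outliers(boards, "search_time", outlier_group_cols)
    after <- dplyr::count(boards, .data$participant_id, name = "n_after")
    n_removed_by <- dplyr::mutate(
      dplyr::left_join(before, after, by = "participant_id"),
      n_excluded_outlier = .data$n_before -
        dplyr::coalesce(.data$n_after, 0L))
  }
  one <- function(d) {
    nh <- d[!d$hint_used, , drop = FALSE]
    has_nh <- nrow(nh) > 0L
    slope <- if (has_nh && dplyr::n_distinct(nh$set_size) >= 2L) {
      coef(lm(search_time ~ set_size, data = nh))[["set_size"]]
    } else NA_real_
    tibble(
      n_boards = nrow(d),
      avg_search_time_with_hints = mean(d$search_time),
      avg_search_time_without_hints = if (has_nh) mean(nh$search_time) else
        NA_real_,
      geometric_mean_search_time = if (has_nh)
        geometric_mean(nh$search_time) else NA_real_,
      processing_time_per_item = if (has_nh)
        mean(nh$search_time / nh$set_size) else NA_real_,
      search_slope = slope,
      n_false_moves = sum(d$n_false),
      n_hints = sum(d$hint_used)
    )
  }
  per <- dplyr::group_modify(
    dplyr::group_by(boards, .data$participant_id, .data$group),
    function(d, key) one(d))
  per <- dplyr::ungroup(per)
  out <- dplyr::left_join(per, completion, by = "participant_id")
  out <- dplyr::relocate(out, "task_completion_time_min",
                         .after = "n_boards")
  if (is.null(n_removed_by)) {
    out$n_excluded_outlier <- 0L
  } else {
    out <- dplyr::left_join(
      out, n_removed_by[, c("participant_id", "n_excluded_outlier")],
      by = "participant_id")
  }
  out
}
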