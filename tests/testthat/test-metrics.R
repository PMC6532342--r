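# Performance indicators: search time, outlier fences, slopes, summaries.

make_log <- function(times, hints = FALSE, set_sizes = 16L,
                     pid = "p1", group = "g1", t = 4L) {
  n <- length(times)
  hints <- rep_len(hints, n)
  set_sizes <- rep_len(set_sizes, n)
  w <- as.integer(sqrt(set_sizes))
  tibble::tibble(
    participant_id = pid, group = group,
    w = w, h = as.integer(set_sizes / w), t = t,
    trial_id = sprintf("tr%02d", (seq_len(n) - 1L) %/% 4L + 1L),
    board_index = (seq_len(n) - 1L) %% 4L + 1L,
    move_number = 1L, r1 = 1L, c1 = 1L, r2 = 1L, c2 = 2L,
    elapsed_time = times, accuracy = "correct", hint_used = hints,
    difficulty_rating = NA_integer_
  )
}

test_that("board search time sums false moves into the correct move", {
  entries <- tibble::tibble(elapsed_time = c(1.2, 0.8, 2.0),
                            accuracy = c("false", "false", "correct"))
  expect_equal(board_search_time(entries), 4.0)
  expect_equal(board_search_time(
    tibble::tibble(elapsed_time = 2.74, accuracy = "correct")), 2.74)
  expect_error(board_search_time(
    tibble::tibble(elapsed_time = c(1, 0), accuracy = c("false", "correct"))),
    "positive")
  expect_error(board_search_time(
    tibble::tibble(elapsed_time = 1, accuracy = "false")), "incomplete")
})

test_that("per-board collapse aggregates times, false moves and hints", {
  log <- dplyr::bind_rows(
    tibble::tibble(participant_id = "p1", group = "g", w = 4L, h = 4L,
                   t = 4L, trial_id = "a", board_index = 1L,
                   move_number = 1:2, r1 = 1L, c1 = 1L, r2 = 1L, c2 = 2L,
                   elapsed_time = c(1.5, 2.5),
                   accuracy = c("false", "correct"),
                   hint_used = c(FALSE, TRUE),
                   difficulty_rating = NA_integer_),
    make_log(3.0)[1, ]
  )
  boards <- board_search_times(log)
  expect_equal(nrow(boards), 2L)
  a <- boards[boards$trial_id == "a", ]
  expect_equal(a$search_time, 4.0)
  expect_equal(a$n_false, 1L)
  expect_true(a$hint_used)
  expect_equal(a$set_size, 16L)
})

test_that("Tukey fences drop far points per group, once", {
  x <- tibble::tibble(search_time = c(1, 2, 2, 3, 20), g = "a")
  kept <- filter_outliers(x, group_cols = "g")
  expect_equal(kept$search_time, c(1, 2, 2, 3))
  expect_equal(attr(kept, "n_removed"), 1L)

  # IQR = 0: fences collapse onto the common value, nothing is removed
  same <- tibble::tibble(search_time = rep(5, 6))
  expect_equal(nrow(filter_outliers(same)), 6L)

  # groups are filtered independently
  two <- tibble::tibble(search_time = c(1, 2, 2, 3, 20, 18, 19, 20, 21, 2),
                        g = rep(c("a", "b"), each = 5))
  kept <- filter_outliers(two, group_cols = "g")
  expect_equal(kept$search_time[kept$g == "a"], c(1, 2, 2, 3))
  expect_equal(kept$search_time[kept$g == "b"], c(18, 19, 20, 21))

  # tiny groups pass through with a warning
  expect_warning(out <- filter_outliers(
    tibble::tibble(search_time = c(1, 100, 3))), "fewer than 4")
  expect_equal(nrow(out), 3L)
})

test_that("processing time per item inverts exactly", {
  expect_equal(processing_time_per_item(4.0, c(4, 4, 4)), 0.25)
  expect_equal(processing_time_per_item(0, set_size = 30), 0)
  set.seed(14)
  st <- runif(200, 0.1, 30)
  ss <- sample(c(16, 20, 25, 36, 64), 200, replace = TRUE)
  expect_equal(processing_time_per_item(st, set_size = ss) * ss, st,
               tolerance = 1e-9)
})

test_that("search slope recovers exact linear and constant data", {
  d <- tibble::tibble(set_size = rep(c(16, 25, 36, 49, 64), each = 4))
  d$search_time <- 0.1 * d$set_size
  fit <- search_slope(d)
  # noiseless data: summary.lm warns about the perfect fit, which is
  # exactly the point here
  expect_equal(suppressWarnings(tidy(fit)$slope), 0.1, tolerance = 1e-12)
  expect_equal(suppressWarnings(glance(fit)$nobs), 20L)

  d$search_time <- 3
  expect_equal(suppressWarnings(tidy(search_slope(d))$slope), 0,
               tolerance = 1e-12)

  expect_error(search_slope(tibble::tibble(set_size = rep(16, 5),
                                           search_time = 1:5)),
               "2 distinct set sizes")

  # grouped fits return one slope per group, and the gamma GLM runs
  d2 <- tibble::tibble(set_size = rep(c(16, 25, 36), times = 20),
                       g = rep(c("a", "b"), each = 30))
  set.seed(3)
  d2$search_time <- (1 + 0.1 * d2$set_size) *
    ifelse(d2$g == "a", 1, 2) * rgamma(60, 4, 4)
  fit2 <- search_slope(d2, group_col = "g", gamma_glm = TRUE)
  expect_equal(nrow(tidy(fit2)), 2L)
  expect_s3_class(fit2$gamma_fit, "glm")
  expect_s3_class(autoplot(fit2), "ggplot")
})

test_that("session summaries follow the hint-exclusion contract", {
  log <- make_log(c(1, 4), hints = FALSE)
  s <- summarize_session(log)
  expect_equal(s$avg_search_time_with_hints, 2.5)
  expect_equal(s$avg_search_time_without_hints, 2.5)
  expect_equal(s$geometric_mean_search_time, 2.0)
  expect_equal(s$task_completion_time_min, 5 / 60)
  expect_equal(s$n_false_moves, 0L)
  expect_equal(s$processing_time_per_item, 2.5 / 16)

  # hinted boards leave the without-hints side
  log2 <- make_log(c(1, 4), hints = c(FALSE, TRUE))
  s2 <- summarize_session(log2)
  expect_equal(s2$avg_search_time_with_hints, 2.5)
  expect_equal(s2$avg_search_time_without_hints, 1)
  expect_equal(s2$n_hints, 1L)

  # every board hinted: without-hints statistics are missing, not zero
  log3 <- make_log(c(1, 4), hints = TRUE)
  s3 <- summarize_session(log3)
  expect_true(is.na(s3$avg_search_time_without_hints))
  expect_true(is.na(s3$geometric_mean_search_time))

  expect_error(summarize_session(make_log(numeric(0))), "empty")
})

test_that("outlier filtering inside summaries counts exclusions", {
  log <- make_log(c(1, 2, 2, 3, 40, 2, 3, 2))
  s <- summarize_session(log, remove_outliers = TRUE)
  expect_equal(s$n_excluded_outlier, 1L)
  expect_equal(s$n_boards, 7L)
  # completion time covers all moves, before any exclusion
  expect_equal(s$task_completion_time_min, sum(log$elapsed_time) / 60)
})

test_that("geometric mean never exceeds the arithmetic mean", {
  set.seed(9)
  for (i in 1:50) {
    x <- rgamma(sample(3:40, 1), shape = runif(1, 0.5, 5),
                rate = runif(1, 0.1, 2))
    expect_lte(exp(mean(log(x))), mean(x) + 1e-12)
    log1 <- make_log(x)
    s <- summarize_session(log1)
    expect_lte(s$geometric_mean_search_time,
               s$avg_search_time_without_hints + 1e-12)
  }
})
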