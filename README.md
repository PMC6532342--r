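# searchmatch

Build, validate, play and score an experimentally controlled match-3
visual search task.

Classic tile-matching match-3 games exercise visual search — finding a
spatial configuration of identical tiles among distractors — but
commercial games neither control task difficulty nor expose performance
data. `searchmatch` implements the task-engineering side of a
*taskified* match-3 game for researchers in cognitive assessment and
aging: every puzzle board is constructed so that it contains **exactly
one** valid move (single-target search), difficulty is manipulated
through two classic visual-search variables, and every attempted move is
logged with its timing.

The two difficulty variables are:

* **set size** `w × h` — the number of tiles on the board (width and
  height each range over 4–8, 25 board sizes);
* **distractor heterogeneity** `t` — the number of distinct tile types,
  ranging from 4 to `max(w, h)`.

The restricted factorial crossing `(w, h, t) ∈ {4..8} × {4..8} ×
{4 ≤ t ≤ max(w, h)}` yields 95 difficulty levels. A *playable trial* is
a sequence of 4 consecutive boards: solving the unique move on board *i*
removes the matched line of 3, tiles fall, sampled refill tiles enter
from the top, and the refilled board again contains exactly one target.

A *target pattern* is a configuration of 3 identical tiles that one
adjacent swap turns into a line of 3. Up to translation there are 16 of
them, falling into 3 families under the symmetries of the square:
**J** (move a tile diagonally next to a pair), **V** (move between two
identical tiles) and **i** (move toward a pair).

From move logs the package computes the standard visual-search
indicators: per-board **search time** (false moves summed into the
correct move), **processing time per item** (search time / set size),
the **search slope** (seconds per item of set size, by OLS with an
optional gamma-GLM cross-check), geometric mean search time, and
false-move / hint counts, with Tukey-fence (1.5 × IQR) outlier
filtering.

## Worked example

Generate a trial, inspect its unique move, then simulate two groups of
synthetic players and score their logs:

```r
library(searchmatch)

trial <- generate_trial(c(5, 5, 5), seed = 2024)
trial$initial_board
#> <smt_board 5x5, 5 tile types>
#>   3 1 4 3 1
#>   3 3 0 4 4
#>   4 4 0 1 4
#>   0 2 3 2 0
#>   0 1 4 1 2
enumerate_valid_moves(trial$initial_board)
#> # A tibble: 1 × 4
#>      r1    c1    r2    c2
#> 1     1     3     2     3
```

Swapping cells (1,3) and (2,3) drops the 4 into the pair of 0s — a
J-pattern — and is the only move on the board that creates a match.
The trial's remaining three boards satisfy the same property
(`validate_trial(trial)` replays and checks all of them).

```r
models <- list(player_model(label = "young", group_multiplier = 1),
               player_model(label = "older", group_multiplier = 1.6))
trials <- c(generate_trials(c(4, 4, 4), n = 2, seed = 11),
            generate_trials(c(5, 5, 4), n = 3, seed = 12),
            generate_trials(c(6, 6, 5), n = 2, seed = 13))
log <- simulate_cohort(models, trials, n_per_group = 20, seed = 99)

summary_tbl <- summarize_session(log)
dplyr::summarise(dplyr::group_by(summary_tbl, group),
                 mean_search = mean(avg_search_time_without_hints),
                 geo = mean(geometric_mean_search_time))
#> # A tibble: 2 × 3
#>   group mean_search   geo
#> 1 older        4.21  3.60
#> 2 young        2.55  2.22

fit <- search_slope(board_search_times(log), group_col = "group")
tidy(fit)
#> # A tibble: 2 × 5
#>   group  slope slope_se intercept intercept_se
#> 1 older 0.122   0.0120      1.10         0.321
#> 2 young 0.0715  0.00726     0.722        0.194
```

The simulated "older" group is configured 1.6× slower; the recovered
mean search times (4.21 vs 2.55 s) and search slopes (0.122 vs 0.072
s/item) show the metrics pipeline picking that up from raw move logs.
`autoplot(fit)` draws search time against set size with the fitted
lines; `autoplot()` also works on boards and playability surveys.

Trials round-trip through a canonical plain-text format
(`write_trial()` / `read_trial()`), move logs through CSV
(`write_session_log()` / `read_session_log()`), and live play goes
through `start_trial()`, `submit_move()`, `request_hint()` and
`record_difficulty_rating()`.

## Vignette

`vignettes/searchmatch-methods.Rmd` documents the model and the design
decisions: the single-target acceptance rule, generator budgets and
backtracking, the pattern taxonomy and its counting conventions, the
metric definitions (outlier fences, slope estimators, hint exclusion)
and what the synthetic player does and does not emulate.
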