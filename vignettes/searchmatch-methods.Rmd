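---
title: "Methods: a single-target match-3 visual search task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a single-target match-3 visual search task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchmatch)
```

## The task

Match-3 games present a grid of colored tiles; the player swaps two
orthogonally adjacent tiles to align three identical ones, which are
then removed and replaced. Finding a swap is a visual search problem:
the target is a *spatial configuration* of identical tiles, embedded
among distractor tiles, and the two classic difficulty variables of the
visual search paradigm map directly onto the game. Set size is the
number of tiles on the board (`w * h`), and distractor heterogeneity is
the number of distinct tile types `t`: with few types, many tiles share
the target's identity ("sharing") and near-miss configurations abound;
with many types the board is more heterogeneous and targets stand out
("grouping").

`searchmatch` implements this task in a fully controlled form. Every
board of every trial contains **exactly one** valid move, so per-board
search time is unambiguous: the interval from board onset to the
correct swap, including any false moves in between. A trial is four
consecutive single-target boards linked by the solved match and a
searched refill; a session plays trials, logs every attempted swap, and
the metrics layer turns the logs into the standard search indicators.

## Board mechanics

A board is an `h x w` integer matrix of tile ids `0:(t-1)` with row 1
at the top; gravity moves tiles toward larger row indices and refill
tiles enter at row 1. A *run* is a maximal horizontal or vertical
sequence of three or more identical tiles; a board with no runs is
*stable*. A *move* is an unordered swap of two orthogonally adjacent
cells and is *valid* exactly when it creates at least one run. Swapping
two identical tiles changes nothing and is never valid (in a session it
still counts as a false move — a genuine, futile swap attempt).
Resolution removes all run cells, drops survivors column-wise
preserving order, and fills the holes from per-column refill streams
whose first element ends highest.

The core mechanics stay general: a swap creating a run longer than 3,
or two runs at once, resolves correctly. It is the *generator* that
excludes such boards, because an unambiguous hint and search time
require a unique, single-line match. The inner loops (run scan, swap
enumeration) are compiled (Rcpp); everything else is plain R.

Coordinates are 1-based `(row, col)` throughout — the natural R
convention — and the trial file format serializes them as such; tile
ids stay 0-based.

## The pattern taxonomy

`enumerate_target_templates()` does not hard-code the taxonomy: it
enumerates every 3-cell configuration in a 4 x 4 window, asks which
single moves of one tile onto an adjacent free cell complete a line of
three, and keeps configurations with exactly one completing move.
Deduplicated up to translation — rotations and reflections counted
separately, which is the counting convention that makes the answer
16 — this yields 16 templates. Their orbits under the eight symmetries
of the square are exactly the three classic families: J (8 members,
move diagonally from a pair), V (4, move between two identical tiles)
and i (4, move along the line toward a pair).

The template set powers an independent counting route:
`count_target_moves()` slides each template over the board and counts
distinct completing moves, while `enumerate_valid_moves()` brute-forces
every adjacent swap. The two are interchangeable by construction (any
valid swap induces a template hit on some triple through the moved
tile, and any template hit is a valid swap on a stable board), and the
test suite holds them equal on tens of thousands of random stable
boards. The trial validator deliberately uses only the swap route, so
generator and validator never share the template code.

Distractor (false-target) patterns — a pair plus a third identical tile
displaced by one cell, admitting no completing swap — are enumerated
best-effort by `enumerate_distractor_templates()`: each target
template's tiles are displaced by one orthogonal step and candidates
are kept when they contain an adjacent pair, are neither a line nor a
target, and admit no completing move. Under this rule there are 32
distinct configurations; published taxonomies count 20 under a
displacement convention that is not fully specified, so the package
reports its own count and nothing downstream depends on it.

## The difficulty-level space

`enumerate_level_specs()` builds the restricted factorial space
`(w, h, t) in {4..8} x {4..8} x {4 <= t <= max(w, h)}`: 25 board sizes,
95 levels. "Sorted by set size" is made total by the tie-break
`(set_size, w, h, t)`, used everywhere. `split_parallel_versions()`
duplicates square levels into both parallel versions and deals
rectangular ones out alternately after that sort, so each version
covers every available set size. A shortened version for frail
populations is a configurable subset (the lower end of the sorted
space) rather than a hard-coded list, because no canonical 12-level
subset is fixed by the construction.

## Trial generation

A board is accepted as single-target when it (a) contains no run,
(b) admits exactly one valid move, and (c) that move creates exactly
one run of exactly length 3. Reading "exactly one target pattern" as
"exactly one valid move" guarantees both an unambiguous hint and an
unambiguous search time; forbidding longer or double runs (flag
`forbid_runs_gt3`, default on) keeps every match visually identical —
one line of three — across the whole difficulty space.

Boards are found by rejection sampling uniform random fills (default
budget 10,000 attempts). Trials chain four such boards: after solving
board *i*, refill tiles are sampled uniformly per hole and retried
(default 2,000 attempts per stage) until the refilled board passes
acceptance, backtracking one stage on exhaustion and restarting from a
fresh initial board (default 25 restarts) when a subtree keeps
failing. Everything is driven by one seed, so `(level, seed, config)`
determines the trial byte-for-byte.

Acceptance probability falls steeply with set size at fixed `t`:
random large boards with few tile types carry *many* valid moves, so
demanding exactly one becomes astronomically unlikely — measured
per-sample acceptance drops from about 2.7% at (4,4,4) through 0.05%
at (5,5,4) to effectively zero at (8,8,4). Levels in that corner are
therefore infeasible under any realistic budget, which is an inherent
property of the construction, not a defect: the feasible subset is
what `survey_playability()` computes, using the threshold of 47
distinct playable trials (distinctness = distinct initial boards) as
the feasibility criterion. Feasibility near the boundary depends on
the search budget, so the surveyed set is reported, cached to CSV on
request, and never hard-coded.

## Trial files and validation

Trials serialize to a canonical, self-describing text format (header;
board as `h` lines of `w` ids; four match blocks with the solution
move and one refill line per column; LF endings). Canonical bytes make
hash-based regression tests possible. `read_trial()` re-checks
structure with parse errors naming the offending line;
`validate_trial()` replays the trial with the core mechanics and the
brute-force swap oracle, checking stability, move uniqueness, solution
agreement, the single-run-of-3 property and refill reproduction, and
reports the first violation. `write_trial()` refuses trials that fail
validation.

## Sessions and logging

The engine is headless and timing is injected: each submission carries
its elapsed seconds since the previous event, so a GUI, a script or
the synthetic player can drive it identically. Correct moves resolve
and advance (the trial self-terminates after the fourth); any other
adjacent swap bounces and is logged as a false move. Out-of-bounds or
non-adjacent input is malformed — rejected with an error, not logged —
since only genuine swap attempts are moves. `request_hint()` returns
the unique move and flags the board's eventual correct move with
`hint_used = TRUE`; a 1–10 difficulty rating can be attached after
completion. Logs are one fixed-order row per attempted move and
round-trip through CSV.

## Performance metrics

*Search time* per board sums all elapsed times up to and including the
correct move. *Outlier filtering* uses Tukey fences, `[Q1 - 1.5 IQR,
Q3 + 1.5 IQR]` per group, with type-7 (linear interpolation)
quartiles — the common statistics-software default; the convention
matters at these small samples, so it is fixed and documented. The
filter runs once (no re-iteration), before hint exclusion, and passes
groups of fewer than 4 observations through untouched with a warning.

*Processing time per item* is search time divided by set size, an
exact identity (`ppi * set_size == search_time` to 1e-9 in the tests).
*Search slope* is estimated primarily by OLS of per-board search time
on set size, per group — simple, dependency-light, and unbiased for
the mean-scale slope the simulator defines. A gamma-family GLM with
inverse link and a set size x group interaction is available as a
cross-check (`gamma_glm = TRUE`) because skewed response times are
conventionally modeled that way; it is secondary since link and
contrast conventions vary across analyses. The geometric mean of
hint-free board times is reported for use in correlation analyses.

Hint exclusion is applied at *board* granularity: a board on which a
hint was used leaves the without-hints averages, the geometric mean,
processing time and slope inputs. (Excluding whole 4-board trials is
the other defensible reading; board-level exclusion discards less data
and is what the per-board `hint_used` flag naturally supports.) When
every board was hinted the without-hints statistics are `NA`, never
zero. Overall task completion time covers all moves before any
exclusion.

## The synthetic player

`player_model()` defines the fixture generator's ground truth: search
time on a `(w, h, t)` board is gamma-distributed with shape `k`
(default 4, mildly skewed) and mean
`group_multiplier * max(eps, base_time + set_size_effect * w*h +
tile_type_effect * t)`. The linear mean with a positive set-size
coefficient, a negative tile-type coefficient and ordered group
multipliers is the minimal structure carrying the effect directions
the task is designed to measure. Defaults — `base_time = 1` s,
`set_size_effect = 0.08` s/item, `tile_type_effect = -0.1` s/type,
multiplier 1 — give about 2.5 s mean search time on a 5x5 board with 5
types, a plausible fast-adult figure; slower groups are modeled by
multipliers (e.g. 1.6 and 3), and false moves and hints are rare
per-board events (`p_false = 0.02`, `p_hint = 0.03`). A false move,
when it occurs, splits the board's total time at a uniform point and
is a random non-solution adjacent swap — with exactly one valid move
per board, any other adjacent pair is guaranteed invalid.

`simulate_cohort()` plays real trials through the session engine, so
simulated logs satisfy the replay property by construction;
`simulate_board()` skips the engine and needs only `(w, h, t)`, which
is what large parameter-recovery runs use.

What the simulator does *not* emulate: learning across trials,
target-location and target-type effects, speed–accuracy trade-offs,
motor noise, or any fitted human parameters. Tests passing on
synthetic data therefore certify the pipeline — generation, logging,
metric arithmetic, effect-direction recovery — not the cognitive
validity of the task; group comparisons on real participants are out
of scope for this package.

## Numerical and scale choices

Degenerate inputs are handled explicitly: unstable boards error on
move enumeration (the two facts are kept consistent), empty logs and
incomplete boards error in the metrics, an all-equal sample has
collapsed fences and loses nothing to the outlier filter, and a
single-set-size design refuses a slope. Moves are canonicalized
(lexicographically smaller cell first) so each unordered swap counts
once. All randomness flows through explicit seeds; generator results
are reproducible byte-for-byte.

The test suite exercises the guarantees at these scales, chosen to
make the checks sharp while keeping a full run comfortable on a single
CPU: 1,000 random stable boards per practice-level spec for
swap-oracle equivalence plus 10,000 mixed-spec boards for
template/swap agreement; 100 generated trials at each of (4,4,4),
(5,5,5), (6,6,6) through the replay validator; 47 distinct trials for
the (4,4,4) feasibility check; 2,000 simulated boards for recovering a
0.1 s/item slope to within ±0.03; and 50 simulated participants per
group for the group-ordering check.

## Known limitations

* Feasibility counts near the 47-trial threshold depend on the search
  budget; only the clear interior of the feasible/infeasible split is
  asserted.
* The distractor enumeration is a documented approximation (32
  configurations under this package's displacement rule); it is
  exposed for inspection but carries no generator logic.
* The gamma GLM cross-check can fail to converge on degenerate
  designs; the OLS estimator is the supported primary.
* The package provides no graphical front end; `autoplot()` renderings
  are diagnostics, not stimuli.
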