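# Trial-design combinatorics and schedule construction for both experiments.
#
# A "psychic" (information source) is summarized by the pair (n_acc, n_pos):
# how many of its five example predictions were correct, and how many of them
# were "win" predictions.  Together with the number of true wins w among the
# five example lotteries, not every pair is realizable: every wrong prediction
# on a loss lottery is necessarily a "win" prediction, which couples the three
# counts through a parity rule (see `feasible_profile`).

#' Is a psychic profile realizable for a given number of true wins?
#'
#' Let x be the number of win-lotteries the psychic predicted correctly. Then
#' `n_acc + n_pos + w` must be odd (equivalently `x = (n_acc + n_pos + w - 5)/2`
#' is an integer) and x must satisfy `max(0, n_acc + w - 5) <= x <= min(n_acc, w)`.
#' The minimum-accuracy rule `n_acc >= 3` (which makes inverse inference
#' suboptimal by construction) is enforced as well.
#'
#' @param w number of "win" outcomes among the five example lotteries (0-5).
#' @param n_acc number of correct example predictions (0-5).
#' @param n_pos number of "win" example predictions (0-5).
#' @return logical (vectorized over the arguments).
#' @export
feasible_profile <- function(w, n_acc, n_pos) {
  stopifnot(all(w >= 0 & w <= 5))
  ok <- n_acc >= 3 & n_acc <= 5 & n_pos >= 0 & n_pos <= 5
  two_x <- n_acc + n_pos + w - 5
  ok & (two_x %% 2 == 0) &
    (two_x / 2 >= pmax(0, n_acc + w - 5)) &
    (two_x / 2 <= pmin(n_acc, w))
}

#' Enumerate feasible psychic profiles for a true-win count
#'
#' Returns exactly the (n_acc, n_pos) pairs realizable by some binary
#' prediction pattern over five lotteries with `w` win outcomes, under the
#' minimum-accuracy-of-three rule.  Deterministic and sorted.
#'
#' @param w true-win count, an integer in 0-5.
#' @return a data.frame with columns `n_acc`, `n_pos`, sorted by both.
#' @examples
#' enumerate_profiles(0)  # (3,2), (4,1), (5,0)
#' @export
enumerate_profiles <- function(w) {
  if (length(w) != 1L || is.na(w) || w != as.integer(w) || w < 0 || w > 5) {
    stop("`w` must be a single integer in 0..5")
  }
  grid <- expand.grid(n_acc = 3:5, n_pos = 0:5)
  grid <- grid[feasible_profile(w, grid$n_acc, grid$n_pos), , drop = FALSE]
  grid <- grid[order(grid$n_acc, grid$n_pos), , drop = FALSE]
  data.frame(n_acc = as.integer(grid$n_acc), n_pos = as.integer(grid$n_pos))
}

#' Enumerate all admissible Experiment-1 trial combinations
#'
#' A combination is a true-win count `w` together with an unordered pair of
#' two *distinct* feasible profiles.  The total across `w = 0..5` is asserted
#' to equal 56, the design's admissible-combination count; a mismatch would
#' indicate a broken feasibility rule.
#'
#' @return data.frame with columns `w`, `n_acc_a`, `n_pos_a`, `n_acc_b`,
#'   `n_pos_b`; profile A precedes profile B lexicographically.
#' @export
enumerate_pair_combinations <- function() {
  out <- do.call(rbind, lapply(0:5, function(w) {
    pr <- enumerate_profiles(w)
    n <- nrow(pr)
    if (n < 2L) return(NULL)
    idx <- utils::combn(n, 2L)
    data.frame(w = w,
               n_acc_a = pr$n_acc[idx[1L, ]], n_pos_a = pr$n_pos[idx[1L, ]],
               n_acc_b = pr$n_acc[idx[2L, ]], n_pos_b = pr$n_pos[idx[2L, ]])
  }))
  rownames(out) <- NULL
  stopifnot(nrow(out) == 56L)
  out
}

#' Validate a trial specification
#'
#' Report-style validation: returns a character vector naming every violated
#' invariant (parity/bounds feasibility, minimum accuracy, profile
#' distinctness, Experiment-2 ranges), empty when the trial is valid.
#'
#' @param w true-win count.
#' @param n_acc_a,n_pos_a profile of psychic A (or of the single Experiment-2
#'   psychic).
#' @param n_acc_b,n_pos_b profile of psychic B; leave `NA` for Experiment 2.
#' @param experiment 1 or 2; Experiment 2 additionally requires `w` in
#'   \{2, 3\} and `n_acc` in \{3, 4\}.
#' @return character vector of violations (possibly empty).
#' @export
validate_trial <- function(w, n_acc_a, n_pos_a, n_acc_b = NA, n_pos_b = NA,
                           experiment = 1) {
  bad <- character(0)
  if (is.na(w) || w < 0 || w > 5) {
    return("w outside 0..5")
  }
  check_one <- function(nm, na, np) {
    msgs <- character(0)
    if (is.na(na) || is.na(np)) return(sprintf("profile %s incomplete", nm))
    if (na < 3) msgs <- c(msgs, sprintf("profile %s: n_acc < 3 (minimum-accuracy rule)", nm))
    if (na > 5 || np < 0 || np > 5) msgs <- c(msgs, sprintf("profile %s: counts outside 0..5", nm))
    if ((na + np + w) %% 2 == 0) {
      msgs <- c(msgs, sprintf("profile %s: parity violation (n_acc + n_pos + w must be odd)", nm))
    } else if (na >= 3 && na <= 5 && np >= 0 && np <= 5 &&
               !feasible_profile(w, na, np)) {
      msgs <- c(msgs, sprintf("profile %s: infeasible for w = %d (bound on correctly predicted wins)", nm, w))
    }
    msgs
  }
  bad <- c(bad, check_one("A", n_acc_a, n_pos_a))
  if (experiment == 1) {
    bad <- c(bad, check_one("B", n_acc_b, n_pos_b))
    if (!anyNA(c(n_acc_a, n_pos_a, n_acc_b, n_pos_b)) &&
        n_acc_a == n_acc_b && n_pos_a == n_pos_b) {
      bad <- c(bad, "profiles A and B identical")
    }
  } else {
    if (!w %in% c(2, 3)) bad <- c(bad, "Experiment 2 requires w in {2, 3}")
    if (!is.na(n_acc_a) && !n_acc_a %in% c(3, 4)) {
      bad <- c(bad, "Experiment 2 requires n_acc in {3, 4}")
    }
  }
  bad
}

#' Validate every row of a schedule or dataset
#'
#' @param data a data.frame with the schedule columns of either experiment.
#' @return a list of per-row violation vectors; `all(lengths(...) == 0)` iff
#'   the whole table is valid.
#' @export
validate_schedule <- function(data) {
  exp2 <- !("n_acc_b" %in% names(data)) || all(is.na(data$n_acc_b))
  acc_a <- if ("n_acc_a" %in% names(data)) data$n_acc_a else data$n_acc
  pos_a <- if ("n_pos_a" %in% names(data)) data$n_pos_a else data$n_pos
  lapply(seq_len(nrow(data)), function(r) {
    validate_trial(data$w[r], acc_a[r], pos_a[r],
                   if (exp2) NA else data$n_acc_b[r],
                   if (exp2) NA else data$n_pos_b[r],
                   experiment = if (exp2) 2 else 1)
  })
}

#' Default 16-combination Experiment-1 trial set
#'
#' The original design used a manually curated 16-combination subset of the 56
#' admissible combinations (not published), so this default is a documented
#' stratified stand-in: it covers every true-win count, both equal- and
#' unequal-accuracy pairs, and both orderings of accuracy versus positivity
#' advantage.  Fully replaceable by any valid combination table.
#'
#' @return data.frame of 16 rows in the `enumerate_pair_combinations` format.
#' @export
default_exp1_combos <- function() {
  m <- matrix(c(
    0, 3, 2, 4, 1,
    0, 4, 1, 5, 0,
    1, 3, 1, 3, 3,
    1, 4, 0, 4, 2,
    1, 3, 3, 5, 1,
    2, 3, 0, 3, 4,
    2, 4, 1, 4, 3,
    2, 3, 4, 5, 2,
    2, 3, 0, 4, 3,
    3, 3, 1, 3, 5,
    3, 4, 2, 4, 4,
    3, 3, 5, 5, 3,
    3, 3, 1, 4, 4,
    4, 3, 2, 4, 5,
    4, 3, 4, 5, 4,
    5, 3, 3, 4, 4), ncol = 5, byrow = TRUE)
  out <- data.frame(w = m[, 1], n_acc_a = m[, 2], n_pos_a = m[, 3],
                    n_acc_b = m[, 4], n_pos_b = m[, 5])
  stopifnot(all(lengths(validate_schedule(out)) == 0))
  out
}

#' Default Experiment-2 combination set
#'
#' All feasible (w, profile) combinations with `w` in \{2, 3\} and `n_acc` in
#' \{3, 4\}; the brute-force enumeration yields 10 combinations, hence
#' 40 trials once each is repeated four times.
#'
#' @return data.frame with columns `w`, `n_acc`, `n_pos`.
#' @export
default_exp2_combos <- function() {
  out <- do.call(rbind, lapply(c(2, 3), function(w) {
    pr <- enumerate_profiles(w)
    pr <- pr[pr$n_acc %in% c(3, 4), , drop = FALSE]
    cbind(w = w, pr)
  }))
  rownames(out) <- NULL
  out
}

#' Build a randomized Experiment-1 schedule
#'
#' Each combination appears exactly once per block; trial order and the
#' left/right position of psychic A are randomized within block.
#'
#' @param combos combination table (default [default_exp1_combos()]).
#' @param n_blocks number of blocks (the experiment used 4).
#' @param seed optional integer for a reproducible schedule.
#' @param participant_id id stamped on every row.
#' @return data.frame, one row per trial: `participant_id`, `experiment`,
#'   `block`, `trial_index`, `w`, profile columns, `side_of_a`.
#' @export
build_exp1_schedule <- function(combos = default_exp1_combos(), n_blocks = 4,
                                seed = NULL, participant_id = 1L) {
  stopifnot(n_blocks >= 1)
  viol <- validate_schedule(combos)
  if (any(lengths(viol) > 0)) {
    stop("invalid combination(s): ",
         paste(unlist(viol), collapse = "; "))
  }
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      ord <- sample.int(nrow(combos))
      blk <- combos[ord, , drop = FALSE]
      blk$block <- b
      blk$side_of_a <- sample(c("left", "right"), nrow(blk), replace = TRUE)
      blk
    }))
    rows$participant_id <- participant_id
    rows$experiment <- 1L
    rows$trial_index <- seq_len(nrow(rows))
    rownames(rows) <- NULL
    rows[, c("participant_id", "experiment", "block", "trial_index", "w",
             "n_acc_a", "n_pos_a", "n_acc_b", "n_pos_b", "side_of_a")]
  })
}

#' Build a pseudo-randomized Experiment-2 schedule
#'
#' Each (w, profile) combination is repeated four times: exactly two
#' repetitions carry a "win" own-lottery prediction (`dir_prediction = 1`) and
#' two a "loss" prediction, with two repetitions placed in blocks 1-2 and two
#' in blocks 3-4 (one prediction of each direction per half).
#'
#' @param combos combination table (default [default_exp2_combos()]).
#' @param seed optional integer seed.
#' @param participant_id id stamped on every row.
#' @return data.frame, one row per trial, with `dir_prediction` and
#'   `repetition` columns.
#' @export
build_exp2_schedule <- function(combos = default_exp2_combos(), seed = NULL,
                                participant_id = 1L) {
  if (!all(combos$w %in% c(2, 3))) stop("Experiment 2 requires w in {2, 3}")
  if (!all(combos$n_acc %in% c(3, 4))) stop("Experiment 2 requires n_acc in {3, 4}")
  if (!all(feasible_profile(combos$w, combos$n_acc, combos$n_pos))) {
    stop("infeasible (w, profile) combination")
  }
  with_seed(seed, {
    per_combo <- lapply(seq_len(nrow(combos)), function(k) {
      # one win- and one loss-prediction in each experiment half
      h1 <- data.frame(block = sample(1:2), dir_prediction = sample(c(1L, 0L)))
      h2 <- data.frame(block = sample(3:4), dir_prediction = sample(c(1L, 0L)))
      reps <- rbind(h1, h2)
      reps$repetition <- seq_len(4L)
      cbind(combos[rep(k, 4L), c("w", "n_acc", "n_pos")], reps)
    })
    rows <- do.call(rbind, per_combo)
    # shuffle within block
    rows <- rows[order(rows$block, sample.int(nrow(rows))), , drop = FALSE]
    rows$participant_id <- participant_id
    rows$experiment <- 2L
    rows$trial_index <- seq_len(nrow(rows))
    rownames(rows) <- NULL
    rows[, c("participant_id", "experiment", "block", "trial_index", "w",
             "n_acc", "n_pos", "dir_prediction", "repetition")]
  })
}

#' Sample an own-lottery prediction from a psychic
#'
#' In Experiment 1 the chosen psychic predicts "win" for the participant's
#' own lottery with probability proportional to its example positivity:
#' `P(win) = n_pos / 5`.
#'
#' @param n_pos positivity count(s) of the chosen psychic(s), 0-5.
#' @param seed optional seed.
#' @return integer vector of 0/1 predictions, one per element of `n_pos`.
#' @export
sample_own_prediction <- function(n_pos, seed = NULL) {
  stopifnot(all(n_pos >= 0 & n_pos <= 5))
  with_seed(seed, rbinom(length(n_pos), 1L, n_pos / 5))
}
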