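# Trial-design combinatorics against the 32-pattern brute-force oracle, and
# the schedule invariants.

test_that("enumerate_profiles matches the brute-force oracle for every w", {
  for (w in 0:5) {
    expect_identical(enumerate_profiles(w), oracle_profiles(w),
                     info = paste("w =", w))
  }
  # frozen spot checks
  expect_identical(enumerate_profiles(0),
                   data.frame(n_acc = 3:5, n_pos = c(2L, 1L, 0L)))
  expect_identical(enumerate_profiles(5),
                   data.frame(n_acc = 3:5, n_pos = 3:5))
  expect_equal(nrow(enumerate_profiles(2)), 6)
  expect_error(enumerate_profiles(6), "0\\.\\.5")
  expect_error(enumerate_profiles(-1), "0\\.\\.5")
})

test_that("feasible n_pos values form a step-2 arithmetic sequence (parity law)", {
  for (w in 0:5) {
    pr <- oracle_profiles(w)
    for (a in unique(pr$n_acc)) {
      np <- sort(pr$n_pos[pr$n_acc == a])
      if (length(np) > 1) expect_true(all(diff(np) == 2))
    }
  }
  expect_equal(sum(sapply(0:5, function(w) nrow(enumerate_profiles(w)))), 28)
})

test_that("pair combinations total 56 with per-w counts C(n_w, 2)", {
  pairs <- enumerate_pair_combinations()
  expect_equal(nrow(pairs), 56)
  counts <- table(pairs$w)
  for (w in 0:5) {
    nw <- nrow(oracle_profiles(w))
    expect_equal(unname(counts[as.character(w)]), choose(nw, 2))
  }
  # distinctness and order within pair
  expect_true(all(pairs$n_acc_a != pairs$n_acc_b | pairs$n_pos_a != pairs$n_pos_b))
  expect_true(all(lengths(validate_schedule(pairs)) == 0))
})

test_that("validate_trial flags the documented violations", {
  expect_length(validate_trial(0, 3, 2, 4, 1), 0)
  expect_match(validate_trial(0, 3, 3, 4, 1), "parity", all = FALSE)
  expect_match(validate_trial(1, 2, 1, 3, 0), "n_acc < 3", all = FALSE)
  expect_match(validate_trial(0, 3, 2, 3, 2), "identical", all = FALSE)
  expect_match(validate_trial(4, 3, 2, NA, NA, experiment = 2),
               "w in \\{2, 3\\}", all = FALSE)
  expect_equal(validate_trial(7, 3, 2, 4, 1), "w outside 0..5")
})

test_that("exp1 schedules have the right shape and are seed-reproducible", {
  sched <- build_exp1_schedule(seed = 11)
  expect_equal(nrow(sched), 64)
  expect_equal(as.integer(table(sched$block)), rep(16L, 4))
  # every combo exactly once per block, whatever the seed
  key <- function(d) sort(paste(d$w, d$n_acc_a, d$n_pos_a, d$n_acc_b, d$n_pos_b))
  combos <- default_exp1_combos()
  for (b in 1:4) {
    expect_equal(key(sched[sched$block == b, ]), key(combos))
  }
  expect_identical(build_exp1_schedule(seed = 11), sched)
  expect_false(identical(build_exp1_schedule(seed = 12), sched))
  expect_true(all(sched$side_of_a %in% c("left", "right")))
  one <- build_exp1_schedule(default_exp1_combos()[1, ], n_blocks = 1, seed = 1)
  expect_equal(nrow(one), 1)
})

test_that("exp2 schedules balance prediction direction across repetitions and halves", {
  sched <- build_exp2_schedule(seed = 5)
  expect_equal(nrow(sched), 40)   # 10 feasible combos x 4 repetitions
  expect_equal(nrow(default_exp2_combos()), 10)
  by_combo <- split(sched, paste(sched$w, sched$n_acc, sched$n_pos))
  for (cb in by_combo) {
    expect_equal(sum(cb$dir_prediction), 2)
    expect_equal(sum(cb$block <= 2), 2)
    expect_equal(sum(cb$block >= 3), 2)
  }
  expect_identical(build_exp2_schedule(seed = 5), sched)
  expect_true(all(lengths(validate_schedule(sched)) == 0))
  bad <- data.frame(w = 4, n_acc = 3, n_pos = 2)
  expect_error(build_exp2_schedule(bad), "w in \\{2, 3\\}")
  bad2 <- data.frame(w = 2, n_acc = 5, n_pos = 2)
  expect_error(build_exp2_schedule(bad2), "n_acc in \\{3, 4\\}")
})

test_that("own-lottery predictions are Bernoulli(n_pos / 5)", {
  expect_equal(sample_own_prediction(rep(5, 100)), rep(1L, 100))
  expect_equal(sample_own_prediction(rep(0, 100)), rep(0L, 100))
  freq <- mean(sample_own_prediction(rep(2, 10000), seed = 99))
  expect_lt(abs(freq - 0.4), 0.01)
})
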