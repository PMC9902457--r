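# Choice-model likelihood machinery against closed forms and a brute-force
# per-trial oracle.

test_that("centering subtracts the pooled mean and is idempotent", {
  d <- data.frame(participant_id = 1, n_acc_a = c(4, 4), n_pos_a = c(1, 3),
                  n_acc_b = c(4, 4), n_pos_b = c(3, 1))
  cd <- center_covariates(d)
  expect_equal(cd$n_acc_a_c, c(0, 0))
  expect_equal(attr(cd, "centering")$pos_offset, 2)
  d2 <- data.frame(participant_id = 1, n_acc_a = c(3, 5), n_pos_a = c(0, 0),
                   n_acc_b = c(5, 3), n_pos_b = c(0, 0))
  cd2 <- center_covariates(d2)
  expect_equal(cd2$n_acc_a_c, c(-1, 1))
  expect_identical(center_covariates(cd2)$n_acc_a_c, cd2$n_acc_a_c)
  expect_error(center_covariates(d[0, ]), "empty")
})

test_that("source_value implements the four model variants", {
  expect_equal(source_value("acc_pos", 1, 0.5, 1, 2), 2.0)
  expect_equal(source_value("pos_only", 9, 0, 1, 2), 0)
  # tiebreak with unequal accuracy reduces to the accuracy-only value
  expect_equal(source_value("tiebreak", 1.3, 0.7, 2, 3, eq = 0),
               source_value("acc_only", 1.3, 0.7, 2, 3))
  expect_equal(source_value("tiebreak", 1.3, 0.7, 2, 3, eq = 1),
               1.3 * 2 + 0.7 * 3)
})

test_that("choice_probability matches the closed form and is stable", {
  expect_equal(choice_probability(1, 1, 3), 0.5)
  expect_equal(choice_probability(2, -7, 0), 0.5)
  expect_equal(choice_probability(1, 0, 1), 1 / (1 + exp(-1)), tolerance = 1e-4)
  # saturation without overflow
  p <- choice_probability(1e6, 0, 5)
  expect_true(p > 0.999999 && p <= 1 && is.finite(p))
  expect_gt(choice_probability(1, 0, 5), choice_probability(0.5, 0, 5))
  expect_error(choice_probability(1, 0, 6), "\\[0, 5\\]")
})

test_that("choice_loglik agrees with the brute-force oracle and its closed forms", {
  data <- make_choice_fixture()
  for (model in c("acc_pos", "acc_only", "pos_only", "tiebreak")) {
    params <- data.frame(k_acc = 1.4, k_pos = -0.6, beta = 2.2)
    ll <- choice_loglik(model, params, data)
    orc <- oracle_choice_loglik(model, 1.4, -0.6, 2.2, data)
    expect_equal(ll$pointwise, orc, tolerance = 1e-10, info = model)
    expect_equal(ll$total, sum(orc), tolerance = 1e-10)
  }
  # beta = 0: n * log(0.5)
  ll0 <- choice_loglik("acc_pos", data.frame(k_acc = 1, k_pos = 1, beta = 0), data)
  expect_equal(ll0$total, nrow(data) * log(0.5))
  expect_error(choice_loglik("acc_pos", data.frame(k_acc = 1, k_pos = 1, beta = 2),
                             transform(data, chose_a = NA)),
               "chose_a")
})

test_that("k_pos = 0 nests acc_only, and label swapping leaves the loglik invariant", {
  data <- make_choice_fixture()
  p_full <- data.frame(k_acc = 1.7, k_pos = 0, beta = 1.1)
  p_acc <- data.frame(k_acc = 1.7, k_pos = NA, beta = 1.1)
  expect_equal(choice_loglik("acc_pos", p_full, data)$total,
               choice_loglik("acc_only", p_acc, data)$total, tolerance = 1e-12)
  # swap the A/B labels together with the recorded choice
  sw <- data
  sw[, c("n_acc_a", "n_pos_a", "n_acc_b", "n_pos_b")] <-
    data[, c("n_acc_b", "n_pos_b", "n_acc_a", "n_pos_a")]
  sw$chose_a <- 1 - data$chose_a
  p <- data.frame(k_acc = 0.8, k_pos = 0.3, beta = 2.5)
  expect_equal(choice_loglik("acc_pos", p, sw)$total,
               choice_loglik("acc_pos", p, data)$total, tolerance = 1e-12)
})

test_that("simulate_choices is deterministic under a seed and saturates correctly", {
  sched <- do.call(rbind, lapply(1:40, function(i) {
    build_exp1_schedule(seed = i, participant_id = i)
  }))
  p_sat <- data.frame(k_acc = 10, k_pos = 0, beta = 5)
  sim <- simulate_choices("acc_pos", p_sat, sched, seed = 3)
  uneq <- sim$n_acc_a != sim$n_acc_b
  chose_acc <- ifelse(sim$n_acc_a > sim$n_acc_b, sim$chose_a, 1 - sim$chose_a)
  expect_gt(mean(chose_acc[uneq]), 0.99)
  p_rand <- data.frame(k_acc = 10, k_pos = 10, beta = 0)
  sim0 <- simulate_choices("acc_pos", p_rand, sched, seed = 4)
  expect_lt(abs(mean(sim0$chose_a) - 0.5), 0.02)
  expect_identical(simulate_choices("acc_pos", p_sat, sched, seed = 3), sim)
})
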