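# Comparison machinery against hand-computed and grid-search oracles.

test_that("pointwise_loglik has shape (draws, observations) and matches an oracle", {
  data <- make_choice_fixture(seed = 21, n_participants = 3)
  fit <- suppressWarnings(fit_hierarchical("acc_pos", data,
                                           cfg_choice(seed = 2, warmup = 250,
                                                      draws = 200)))
  pw <- pointwise_loglik(fit, data)
  s_tot <- 2 * 200
  expect_equal(dim(pw$ll), c(s_tot, nrow(data)))
  expect_true(all(is.finite(pw$ll)))
  expect_identical(pw$participant, data$participant_id)
  # column means equal a direct per-draw recomputation on a few columns
  m <- as.matrix(fit)
  for (t in c(1L, 17L, nrow(data))) {
    i <- match(data$participant_id[t], fit$participants)
    direct <- vapply(seq_len(s_tot), function(s) {
      oracle_choice_loglik("acc_pos", m[s, sprintf("k_acc[%d]", i)],
                           m[s, sprintf("k_pos[%d]", i)],
                           m[s, sprintf("beta[%d]", i)],
                           data[t, , drop = FALSE])
    }, numeric(1))
    expect_equal(unname(pw$ll[, t]), direct, tolerance = 1e-10)
  }
  # beta = 0 draws give log(0.5) everywhere
  fit0 <- fit
  for (i in 1:3) fit0$draws[, , sprintf("beta[%d]", i)] <- 0
  expect_equal(unname(pointwise_loglik(fit0, data)$ll[1, ]),
               rep(log(0.5), nrow(data)))
  expect_error(pointwise_loglik(fit, transform(data, participant_id = 99)),
               "mismatch")
  expect_error(pointwise_loglik(fit, data[0, ]), "empty")
})

test_that("waic matches the definition on toy matrices and adds over observations", {
  # 2-draw toy: densities .5/.25 for one observation
  ll <- matrix(log(c(0.5, 0.25)), 2, 1)
  w <- waic(ll)
  expect_equal(w$waic, oracle_waic(ll), tolerance = 1e-10)
  expect_equal(w$lppd, log(mean(c(0.5, 0.25))), tolerance = 1e-10)
  expect_equal(w$p_waic, var(log(c(0.5, 0.25))), tolerance = 1e-10)
  # degenerate posterior: p_waic = 0, WAIC = -2 sum log p
  lld <- matrix(log(0.3), 5, 4)
  expect_equal(waic(lld)$p_waic, 0)
  expect_equal(waic(lld)$waic, -2 * 4 * log(0.3))
  # additivity over concatenated observation sets
  set.seed(1)
  a <- matrix(rnorm(40, -1, .3), 4); b <- matrix(rnorm(28, -2, .4), 4)
  expect_equal(waic(cbind(a, b))$waic, waic(a)$waic + waic(b)$waic,
               tolerance = 1e-10)
  expect_equal(waic(cbind(a, b))$waic, oracle_waic(cbind(a, b)), tolerance = 1e-10)
  expect_error(waic(matrix(1, 1, 3)), "2 posterior draws")
})

test_that("stacking weights solve the simplex problem (grid-search oracle)", {
  expect_equal(unname(stacking_weights(matrix(c(-3, -4), 2, 1))), 1)
  # identical models: uniform by convention
  e2 <- cbind(c(-2, -3, -1), c(-2, -3, -1))
  expect_equal(unname(stacking_weights(e2)), c(0.5, 0.5), tolerance = 1e-6)
  # dominated model gets weight 0, dominant weight 1
  ed <- cbind(a = c(-1, -2, -1.5), b = c(-2, -3, -2.5))
  w <- stacking_weights(ed)
  expect_equal(unname(w["a"]), 1, tolerance = 1e-6)
  # random instances against the grid oracle
  set.seed(8)
  for (rep in 1:3) {
    e <- matrix(rnorm(30, -5, 1), 10, 3)
    w <- stacking_weights(e)
    orc <- oracle_stacking_grid(e)
    expect_gte(hedoseek:::stacking_objective(w, e) + 1e-8, orc$value)
    expect_equal(sum(w), 1, tolerance = 1e-8)
    expect_true(all(w >= -1e-12))
  }
  expect_error(stacking_weights(cbind(c(1, NA))), "non-finite")
})

test_that("best-model proportions split ties equally and sum to 1", {
  e <- rbind(c(-1, -2), c(-3, -3))   # two participants, one exact tie
  p <- best_model_proportions(e)
  expect_equal(unname(p), c(0.75, 0.25))
  expect_equal(sum(p), 1)
  ed <- rbind(c(-1, -5), c(-2, -6), c(-0.1, -4))
  expect_equal(unname(best_model_proportions(ed)), c(1, 0))
})

test_that("participant elpd is exchangeable for identical participants and errors on one", {
  sched1 <- build_exp1_schedule(seed = 1, participant_id = 1)
  sched2 <- transform(sched1, participant_id = 2)
  p <- data.frame(participant_id = 1:2, k_acc = c(1.5, 1.5),
                  k_pos = c(.5, .5), beta = c(2, 2))
  data <- simulate_choices("acc_pos", p, rbind(sched1, sched2), seed = 5)
  # make the two participants' data literally identical
  data$chose_a[data$participant_id == 2] <- data$chose_a[data$participant_id == 1]
  data$shown_prediction[data$participant_id == 2] <-
    data$shown_prediction[data$participant_id == 1]
  fit <- suppressWarnings(fit_hierarchical("acc_pos", data,
                                           cfg_choice(seed = 7, warmup = 300,
                                                      draws = 300)))
  el <- participant_elpd(fit, data, method = "tis", inner_draws = 200, seed = 1)
  expect_lt(abs(el[1] - el[2]), 4 * sqrt(sum(attr(el, "mc_se")^2)) + 0.5)
  expect_error(participant_elpd(fit, data[data$participant_id == 1, ]),
               "fold")
})

test_that("posterior predictive checks cover self-generated data and reject empty input", {
  data <- make_choice_fixture(seed = 31, n_participants = 6)
  fit <- suppressWarnings(fit_hierarchical("acc_pos", data,
                                           cfg_choice(seed = 4, warmup = 300,
                                                      draws = 300)))
  ppc <- posterior_predictive_check(fit, data, n_rep = 200, seed = 2)
  expect_true(all(c("pos_pref_equal_acc", "acc_pref_unequal") %in% ppc$statistic))
  # data were generated by the fitted model family: statistics should sit
  # inside the replicated interval
  expect_true(all(ppc$inside))
  expect_error(posterior_predictive_check(fit, data[0, ]), "empty")

  bdata <- make_belief_fixture(seed = 32, n_participants = 5)
  bfit <- suppressWarnings(fit_hierarchical("full", bdata, cfg_belief(seed = 4)))
  bppc <- posterior_predictive_check(bfit, bdata, n_rep = 200, seed = 3)
  expect_true(all(bppc$inside))
})
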