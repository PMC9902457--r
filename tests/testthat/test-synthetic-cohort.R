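# Synthetic cohort generator: moments, determinism, design validity and the
# generative monotonicities the analyses rely on.

test_that("draw_participants matches its hyperparameters and is reproducible", {
  spec <- cohort_spec(10000, "acc_pos", seed = 1)
  p <- draw_participants(spec)
  h <- spec$hypers
  expect_lt(abs(mean(p$k_acc) - h$mu_k_acc), 3 * h$sigma_k_acc / 100)
  expect_lt(abs(sd(p$k_acc) - h$sigma_k_acc), 0.05)
  expect_lt(abs(mean(p$k_pos) - h$mu_k_pos), 3 * h$sigma_k_pos / 100)
  expect_true(all(p$beta >= 0 & p$beta <= 5))
  expect_identical(draw_participants(spec), p)
  # degenerate scales collapse everyone onto the group mean
  spec0 <- cohort_spec(50, "acc_pos",
                       hypers = list(mu_k_acc = 2, sigma_k_acc = 1e-12,
                                     mu_k_pos = 1, sigma_k_pos = 1e-12,
                                     mu_beta = 3, sigma_beta = 1e-12),
                       seed = 2)
  p0 <- draw_participants(spec0)
  expect_equal(p0$k_acc, rep(2, 50), tolerance = 1e-6)
  expect_equal(p0$beta, rep(3, 50), tolerance = 1e-6)
  # belief cohort: sigma_u is positive and Gamma(1, .5)-distributed
  specb <- cohort_spec(10000, "full", seed = 3)
  pb <- draw_participants(specb)
  expect_true(all(pb$sigma_u > 0))
  expect_lt(abs(mean(pb$sigma_u) - 2), 0.1)
})

test_that("generate_exp1 produces 64 valid trials per participant", {
  spec <- cohort_spec(4, "acc_pos", seed = 11)
  data <- generate_exp1(spec)
  expect_equal(as.integer(table(data$participant_id)), rep(64L, 4))
  expect_true(all(lengths(validate_schedule(data)) == 0))
  expect_true(all(data$chose_a %in% 0:1))
  expect_true(all(data$win_estimate >= 0 & data$win_estimate <= 16))
  expect_true(all(data$confidence >= 0 & data$confidence <= 100))
  expect_identical(generate_exp1(cohort_spec(4, "acc_pos", seed = 11)), data)
})

test_that("random responders choose at chance; positivity preference shows in shown wins", {
  spec_r <- cohort_spec(40, "acc_pos", random_responder_fraction = 1, seed = 12)
  data_r <- generate_exp1(spec_r)
  expect_lt(abs(mean(data_r$chose_a) - 0.5), 0.02)
  eq <- data_r$n_acc_a == data_r$n_acc_b
  chose_pos <- ifelse(data_r$n_pos_a > data_r$n_pos_b, data_r$chose_a,
                      1 - data_r$chose_a)
  expect_lt(abs(mean(chose_pos[eq]) - 0.5), 0.03)
  # strong positivity preference yields more shown "win" predictions
  hyp_pos <- list(mu_k_acc = 1, sigma_k_acc = .3, mu_k_pos = 2,
                  sigma_k_pos = .3, mu_beta = 4, sigma_beta = .5)
  hyp_neu <- modifyList(hyp_pos, list(mu_k_pos = 0, sigma_k_pos = 1e-9))
  d_pos <- generate_exp1(cohort_spec(30, "acc_pos", hypers = hyp_pos, seed = 13))
  d_neu <- generate_exp1(cohort_spec(30, "acc_pos", hypers = hyp_neu, seed = 13))
  expect_gt(mean(d_pos$shown_prediction), mean(d_neu$shown_prediction))
})

test_that("generate_exp2 balances direction and expresses the k_sym asymmetry", {
  spec <- cohort_spec(6, "full", seed = 21)
  data <- generate_exp2(spec)
  expect_equal(as.integer(table(data$participant_id)), rep(40L, 6))
  expect_true(all(lengths(validate_schedule(data)) == 0))
  combo_dir <- tapply(data$dir_prediction,
                      paste(data$participant_id, data$w, data$n_acc, data$n_pos),
                      sum)
  expect_true(all(combo_dir == 2))
  # symmetric cohort: no direction effect
  hyp_sym <- list(mu_k_cons = 6, sigma_k_cons = .5, mu_k_acc = 3,
                  sigma_k_acc = .5, mu_k_pos = 0, sigma_k_pos = 1e-9,
                  mu_k_sym = 1, sigma_k_sym = 1e-9)
  d_sym <- generate_exp2(cohort_spec(40, "full", hypers = hyp_sym, seed = 22))
  diff_sym <- mean(d_sym$update[d_sym$dir_prediction == 1]) -
    mean(d_sym$update[d_sym$dir_prediction == 0])
  expect_lt(abs(diff_sym), 0.5)
  # asymmetric cohort: larger updates after win predictions
  hyp_asym <- modifyList(hyp_sym, list(mu_k_sym = 1.5))
  d_asym <- generate_exp2(cohort_spec(40, "full", hypers = hyp_asym, seed = 22))
  expect_gt(mean(d_asym$update[d_asym$dir_prediction == 1]),
            mean(d_asym$update[d_asym$dir_prediction == 0]) + 1)
})
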