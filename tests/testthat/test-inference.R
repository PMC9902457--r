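# Sampler correctness: analytic-gradient checks, closed-form posteriors for
# the generic HMC driver, centered/non-centered equivalence on a toy
# hierarchy, prior-only sampling against direct prior draws, and the
# diagnostics machinery.

test_that("compiled gradients match finite differences (both families)", {
  set.seed(42)
  n <- 3; n_trial <- 25
  pid <- sample(0:(n - 1), n_trial, TRUE)
  d_acc <- as.double(sample(-2:2, n_trial, TRUE))
  d_pos <- as.double(sample(-4:4, n_trial, TRUE))
  y <- rbinom(n_trial, 1, 0.5)
  for (flags in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))) {
    dim_th <- n * (1 + sum(flags)) + 2 * (1 + sum(flags))
    lpg <- function(t) hedoseek:::cpp_choice_lpgrad(t, d_acc, d_pos, y, pid, n,
                                                    flags[1], flags[2])
    th <- rnorm(dim_th, 0, 0.5)
    g <- lpg(th)$grad
    gn <- vapply(seq_len(dim_th), function(j) {
      e <- replace(rep(0, dim_th), j, 1e-6)
      (lpg(th + e)$lp - lpg(th - e)$lp) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(g - gn)), 1e-5)
  }
  dirv <- rbinom(n_trial, 1, 0.5)
  acc <- rnorm(n_trial); pos <- rnorm(n_trial); U <- rnorm(n_trial, 5, 3)
  for (has_pos in c(TRUE, FALSE)) {
    dim_th <- n * (4 + has_pos) + 2 * (3 + has_pos)
    lpg <- function(t) hedoseek:::cpp_belief_lpgrad(t, acc, pos, dirv, U, pid,
                                                    n, has_pos)
    th <- rnorm(dim_th, 0, 0.3)
    g <- lpg(th)$grad
    gn <- vapply(seq_len(dim_th), function(j) {
      e <- replace(rep(0, dim_th), j, 1e-6)
      (lpg(th + e)$lp - lpg(th - e)$lp) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(g - gn)), 1e-4)
  }
})

test_that("the HMC driver recovers a known Gaussian posterior", {
  # N(3, 2^2) target: mean and sd must match to Monte-Carlo accuracy
  lpg <- function(q) list(lp = -0.5 * ((q - 3) / 2)^2, grad = -(q - 3) / 4)
  ch <- hmc_chain(lpg, init = 0, n_warmup = 300, n_draws = 2000, seed = 1)
  expect_lt(abs(mean(ch$draws) - 3), 0.15)
  expect_lt(abs(sd(ch$draws) - 2), 0.15)
  expect_equal(ch$n_divergent, 0)
})

test_that("centered and non-centered toy hierarchies agree in distribution", {
  # two-level model: mu ~ N(0,1); theta_j ~ N(mu, tau) with fixed tau;
  # y_j ~ N(theta_j, 1). Observed y fixed; both parameterizations must give
  # the same posterior for mu and theta (analytically a joint Gaussian).
  y <- c(-1, 0.5, 2)
  tau <- 0.7
  lpg_cent <- function(q) {
    mu <- q[1]; th <- q[-1]
    list(lp = -0.5 * mu^2 - 0.5 * sum(((th - mu) / tau)^2) - 0.5 * sum((y - th)^2),
         grad = c(-mu + sum(th - mu) / tau^2,
                  -(th - mu) / tau^2 + (y - th)))
  }
  lpg_nc <- function(q) {
    mu <- q[1]; z <- q[-1]
    th <- mu + tau * z
    dth <- (y - th)
    list(lp = -0.5 * mu^2 - 0.5 * sum(z^2) - 0.5 * sum((y - th)^2),
         grad = c(-mu + sum(dth), -z + tau * dth))
  }
  c1 <- hmc_chain(lpg_cent, rep(0, 4), 400, 3000, seed = 2)
  c2 <- hmc_chain(lpg_nc, rep(0, 4), 400, 3000, seed = 3)
  th2 <- c2$draws[, 1] + tau * c2$draws[, -1]
  expect_lt(abs(mean(c1$draws[, 1]) - mean(c2$draws[, 1])), 0.08)
  expect_lt(abs(sd(c1$draws[, 1]) - sd(c2$draws[, 1])), 0.08)
  expect_lt(max(abs(colMeans(c1$draws[, -1]) - colMeans(th2))), 0.1)
  expect_lt(max(abs(apply(c1$draws[, -1], 2, sd) - apply(th2, 2, sd))), 0.1)
})

test_that("prior-only fits reproduce the printed hyperpriors", {
  empty <- data.frame(participant_id = integer(0), n_acc_a = integer(0),
                      n_pos_a = integer(0), n_acc_b = integer(0),
                      n_pos_b = integer(0), chose_a = integer(0))
  fit <- suppressWarnings(fit_hierarchical("acc_pos", empty,
                                           cfg_choice(seed = 3, warmup = 400,
                                                      draws = 800),
                                           participants = 1:2))
  m <- as.matrix(fit)
  # mu_k_acc ~ N(0,1); mu_beta ~ N(0,2); sigma ~ Gamma(1, .5) (mean 2)
  expect_lt(abs(mean(m[, "mu_k_acc"])), 0.15)
  expect_lt(abs(sd(m[, "mu_k_acc"]) - 1), 0.2)
  expect_lt(abs(mean(m[, "mu_beta"])), 0.4)
  expect_lt(abs(mean(m[, "sigma_k_acc"]) - 2), 0.5)
  # the individual beta prior marginal, checked against direct sampling
  direct <- local({
    set.seed(77)
    mu <- rnorm(40000, 0, 2); sig <- rgamma(40000, 1, rate = 0.5)
    hedoseek:::rtnorm(40000, mu, sig, 0, 5)
  })
  expect_lt(abs(mean(m[, "beta[1]"]) - mean(direct)), 0.25)
})

test_that("point_estimates shrinks toward the group mean and has one row per participant", {
  data <- make_choice_fixture(seed = 303, n_participants = 8)
  fit <- suppressWarnings(fit_hierarchical("acc_pos", data, cfg_choice(seed = 5)))
  est <- point_estimates(fit)
  expect_equal(nrow(est$individual), 8)
  expect_identical(est$individual$participant_id, fit$participants)
  # partial pooling: posterior-mean spread below per-participant MLE spread
  mle <- vapply(unique(data$participant_id), function(id) {
    di <- data[data$participant_id == id, ]
    opt <- optim(c(1, 0.5, 1), function(p) {
      if (p[3] < 0 || p[3] > 5) return(1e9)
      -choice_loglik("acc_pos",
                     data.frame(k_acc = p[1], k_pos = p[2], beta = p[3]),
                     di)$total
    })
    opt$par[1]
  }, numeric(1))
  expect_lt(sd(est$individual$k_acc), sd(mle) + 1e-9)
  med <- point_estimates(fit, stat = "median")
  expect_equal(nrow(med$individual), 8)
})

test_that("diagnostics flag shifted chains and pass i.i.d. ones; ESS is capped", {
  set.seed(9)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(iid), 1.01)
  shifted <- cbind(rnorm(1000), rnorm(1000) + 3)
  expect_gt(split_rhat(shifted), 1.1)
  expect_lte(ess_basic(iid), 4000)
  expect_gt(ess_basic(iid), 2000)   # near-independent draws
  # anticorrelated-ish draws still capped at the total
  x <- matrix(rnorm(2000), 1000, 2)
  expect_lte(ess_basic(x), 2000)
  # single chain errors at the fit level
  data <- make_choice_fixture(seed = 17, n_participants = 2)
  fit1 <- suppressWarnings(fit_hierarchical(
    "acc_only", data, sampler_config(chains = 1, warmup = 150, draws = 100, seed = 1)))
  expect_error(diagnostics(fit1), "2 chains")
})

test_that("degenerate posterior summaries equal the constant", {
  data <- make_choice_fixture(seed = 404, n_participants = 2)
  fit <- suppressWarnings(fit_hierarchical("acc_only", data,
                                           cfg_choice(seed = 6, warmup = 200,
                                                      draws = 150)))
  fit$draws[, , "k_acc[1]"] <- 1.234
  est <- point_estimates(fit)
  expect_equal(est$individual$k_acc[1], 1.234)
})
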