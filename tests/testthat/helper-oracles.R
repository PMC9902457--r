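# Independent brute-force oracles and tiny fixture builders.  Everything here
# deliberately avoids the package's own computation paths.

# All feasible (n_acc, n_pos) profiles for a true-win count w by enumerating
# every one of the 32 binary prediction patterns over 5 lotteries.
oracle_profiles <- function(w, min_acc = 3) {
  outcome <- c(rep(1, w), rep(0, 5 - w))  # 1 = win
  pats <- as.matrix(expand.grid(rep(list(0:1), 5)))
  acc <- rowSums(pats == matrix(outcome, nrow(pats), 5, byrow = TRUE))
  pos <- rowSums(pats)
  keep <- acc >= min_acc
  u <- unique(data.frame(n_acc = acc[keep], n_pos = pos[keep]))
  u <- u[order(u$n_acc, u$n_pos), ]
  data.frame(n_acc = as.integer(u$n_acc), n_pos = as.integer(u$n_pos))
}

# Plain-R per-trial choice log-likelihood (no shared code with the package).
oracle_choice_loglik <- function(model, k_acc, k_pos, beta, data) {
  sapply(seq_len(nrow(data)), function(t) {
    va <- vb <- 0
    eq <- data$n_acc_a[t] == data$n_acc_b[t]
    if (model %in% c("acc_pos", "acc_only", "tiebreak")) {
      va <- va + k_acc * data$n_acc_a[t]
      vb <- vb + k_acc * data$n_acc_b[t]
    }
    gate <- if (model == "tiebreak") as.numeric(eq) else 1
    if (model %in% c("acc_pos", "pos_only", "tiebreak")) {
      va <- va + k_pos * data$n_pos_a[t] * gate
      vb <- vb + k_pos * data$n_pos_b[t] * gate
    }
    pa <- exp(beta * va) / (exp(beta * va) + exp(beta * vb))
    log(if (data$chose_a[t] == 1) pa else 1 - pa)
  })
}

# Plain-R per-trial belief log-likelihood.
oracle_belief_loglik <- function(model, k_cons, k_acc, k_pos, k_sym, sigma_u,
                                 data) {
  sapply(seq_len(nrow(data)), function(t) {
    lin <- k_cons + k_acc * data$n_acc_c[t] +
      (if (model == "full") k_pos * data$n_pos_c[t] else 0)
    mu <- lin * (1 + (k_sym - 1) * data$dir_prediction[t])
    dnorm(data$update[t], mu, sigma_u, log = TRUE)
  })
}

# Hand-rolled WAIC from the definition.
oracle_waic <- function(ll) {
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  -2 * (lppd - p)
}

# Grid search over the simplex for stacking weights (2-3 models).
oracle_stacking_grid <- function(elpd, step = 0.005) {
  k <- ncol(elpd)
  shift <- apply(elpd, 1, max)
  obj <- function(w) sum(log(exp(elpd - shift) %*% w)) + sum(shift)
  grid <- seq(0, 1, by = step)
  best <- NULL; best_val <- -Inf
  if (k == 2) {
    for (w1 in grid) {
      v <- obj(c(w1, 1 - w1))
      if (v > best_val) { best_val <- v; best <- c(w1, 1 - w1) }
    }
  } else if (k == 3) {
    for (w1 in grid) for (w2 in seq(0, 1 - w1, by = step)) {
      v <- obj(c(w1, w2, 1 - w1 - w2))
      if (v > best_val) { best_val <- v; best <- c(w1, w2, 1 - w1 - w2) }
    }
  } else stop("grid oracle supports 2-3 models")
  list(weights = best, value = best_val)
}

# Small fixed choice dataset (two participants, deterministic design).
make_choice_fixture <- function(seed = 101, n_participants = 2) {
  spec <- cohort_spec(n_participants, "acc_pos", seed = seed)
  generate_exp1(spec)
}

make_belief_fixture <- function(seed = 202, n_participants = 2) {
  spec <- cohort_spec(n_participants, "full", seed = seed)
  generate_exp2(spec)
}

# Test-scale sampler configs (choice geometry mixes faster than the belief
# family, whose lin * k_sym ridge needs longer trajectories).
cfg_choice <- function(seed = 1, warmup = 400, draws = 400) {
  sampler_config(chains = 2, warmup = warmup, draws = draws, seed = seed,
                 L = c(32, 64))
}

cfg_belief <- function(seed = 1, warmup = 900, draws = 500) {
  sampler_config(chains = 2, warmup = warmup, draws = draws, seed = seed,
                 adapt_delta = 0.98, L = c(96, 160))
}
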