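# Model recovery, parameter recovery, and ROPE/HDI hyperparameter assessment.

#' Well-separated generating regimes for recovery studies
#'
#' Strong weights and a high, tight inverse temperature so that the candidate
#' models make clearly distinct predictions — the regime under which the
#' generative model should be identifiable.
#'
#' @param model model id.
#' @return named hyperparameter list.
#' @export
recovery_hypers <- function(model) {
  model <- match.arg(model, c(CHOICE_MODELS, BELIEF_MODELS))
  base_choice <- list(mu_beta = 3, sigma_beta = 0.5)
  switch(model,
    acc_pos  = c(list(mu_k_acc = 2, sigma_k_acc = 0.7,
                      mu_k_pos = 1.2, sigma_k_pos = 0.5), base_choice),
    acc_only = c(list(mu_k_acc = 2.5, sigma_k_acc = 0.7), base_choice),
    pos_only = c(list(mu_k_pos = 2.5, sigma_k_pos = 0.7), base_choice),
    tiebreak = c(list(mu_k_acc = 2.5, sigma_k_acc = 0.7,
                      mu_k_pos = 2, sigma_k_pos = 0.7), base_choice),
    default_hypers(model))
}

#' Model recovery study
#'
#' Simulates cohorts from each generating model, fits every candidate model
#' to each cohort, classifies the cohort by summed leave-one-participant-out
#' elpd (or WAIC), and tallies the generating-by-best-fitting confusion
#' matrix.  Rows sum to `n_sims`.
#'
#' @param models candidate (and generating) model ids, one experiment.
#' @param n_sims simulated cohorts per generating model.
#' @param n_participants cohort size.
#' @param config sampler config for every fit.
#' @param method `"tis"` or `"exact_refit"` elpd, or `"waic"`.
#' @param inner_draws marginalization draws for elpd.
#' @param hypers named list of generating hyperparameters per model
#'   ([recovery_hypers()] by default).
#' @param seed master seed.
#' @return object of class `hs_recovery`: `confusion` matrix plus the
#'   per-cohort criterion values.
#' @export
model_recovery <- function(models = CHOICE_MODELS, n_sims = 2L,
                           n_participants = 15L,
                           config = sampler_config(chains = 2, warmup = 300,
                                                   draws = 300),
                           method = "tis", inner_draws = 50L,
                           hypers = setNames(lapply(models, recovery_hypers), models),
                           seed = 1L) {
  stopifnot(n_sims >= 1)
  confusion <- matrix(0L, length(models), length(models),
                      dimnames = list(generating = models, best = models))
  details <- list()
  for (g in models) {
    for (s in seq_len(n_sims)) {
      sim_seed <- child_seed(seed, 100L * match(g, models) + s)
      spec <- cohort_spec(n_participants, model = g, hypers = hypers[[g]],
                          seed = sim_seed)
      data <- if (spec$experiment == 1L) generate_exp1(spec) else generate_exp2(spec)
      crit <- sapply(models, function(m) {
        fit <- suppressWarnings(fit_hierarchical(m, data, config))
        if (method == "waic") {
          -waic(pointwise_loglik(fit, data))$waic / 2   # larger = better
        } else {
          attr(participant_elpd(fit, data, method = method,
                                inner_draws = inner_draws,
                                seed = child_seed(sim_seed, match(m, models))),
               "total")
        }
      })
      best <- models[which.max(crit)]
      confusion[g, best] <- confusion[g, best] + 1L
      details[[paste(g, s, sep = ".")]] <- crit
    }
  }
  structure(list(confusion = confusion, criterion = details,
                 method = method, n_sims = n_sims), class = "hs_recovery")
}

#' @export
print.hs_recovery <- function(x, ...) {
  cat("Model recovery confusion matrix (rows = generating model):\n")
  print(x$confusion)
  invisible(x)
}

#' Parameter recovery study
#'
#' Simulates a cohort from stated hyperparameters, fits the same model, and
#' correlates true with recovered (posterior-mean) individual parameters;
#' also reports whether each generating hyperparameter lies inside its own
#' 95% credible interval.
#'
#' @param model generating/fitted model id.
#' @param hypers generating hyperparameters.
#' @param n_participants cohort size (>= 10).
#' @param config sampler config.
#' @param seed master seed.
#' @return list: `correlations` (named, per individual parameter), `pairs`
#'   (true vs recovered table), `hyper` (estimate, CI, truth, covered flag)
#'   and the fit.
#' @export
parameter_recovery <- function(model = "acc_pos",
                               hypers = default_hypers(model),
                               n_participants = 30L,
                               config = sampler_config(chains = 2,
                                                       warmup = 500,
                                                       draws = 500),
                               seed = 1L) {
  stopifnot(n_participants >= 10)
  spec <- cohort_spec(n_participants, model = model, hypers = hypers, seed = seed)
  data <- if (spec$experiment == 1L) generate_exp1(spec) else generate_exp2(spec)
  truth <- attr(data, "params")
  fit <- suppressWarnings(fit_hierarchical(model, data, config))
  est <- point_estimates(fit)
  common <- intersect(setdiff(names(truth), c("participant_id", "is_random_responder")),
                      names(est$individual))
  common <- common[vapply(common, function(p) sd(truth[[p]]) > 0, logical(1))]
  pairs <- do.call(rbind, lapply(common, function(p) {
    data.frame(parameter = p, participant_id = truth$participant_id,
               true = truth[[p]], recovered = est$individual[[p]])
  }))
  correlations <- vapply(common, function(p) {
    stats::cor(truth[[p]], est$individual[[p]])
  }, numeric(1))
  hyper <- est$hyper
  hyper$truth <- unlist(hypers)[hyper$parameter]
  hyper$covered <- !is.na(hyper$truth) &
    hyper$truth >= hyper$q2.5 & hyper$truth <= hyper$q97.5
  list(correlations = correlations, pairs = pairs, hyper = hyper, fit = fit)
}

#' Region of practical equivalence for a belief-model hyperparameter
#'
#' The bound is the parameter value at which the maximum change in the
#' predictor produces a 0.1-standard-deviation change in the belief updates:
#' `b = 0.1 * sd_dv / delta_max`, with `delta_max = 5` for positivity (five
#' win-predictions vs five loss-predictions) and `delta_max = 1` for accuracy
#' (four vs three accurate), on the raw-difference scale.
#'
#' @param kind `"positivity"` or `"accuracy"`.
#' @param sd_dv standard deviation of the dependent variable (the quantified
#'   updates), must be positive.
#' @return object of class `hs_rope`: `lower`, `upper`, `delta_max`, `sd_dv`.
#' @export
rope_interval <- function(kind = c("positivity", "accuracy"), sd_dv) {
  kind <- match.arg(kind)
  if (!is.numeric(sd_dv) || length(sd_dv) != 1L || sd_dv <= 0) {
    stop("sd_dv must be a positive number")
  }
  delta_max <- if (kind == "positivity") 5 else 1
  b <- 0.1 * sd_dv / delta_max
  structure(list(lower = -b, upper = b, delta_max = delta_max,
                 sd_dv = sd_dv, kind = kind), class = "hs_rope")
}

#' Highest density interval
#'
#' Narrowest contiguous interval containing the requested posterior mass
#' (sliding window over the sorted draws; assumes unimodality).
#'
#' @param samples numeric draws (at least 100).
#' @param mass probability mass in (0, 1\].
#' @return numeric `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- as.numeric(samples)
  if (length(samples) < 100L) stop("hdi needs at least 100 samples")
  if (mass <= 0 || mass > 1) stop("mass must lie in (0, 1]")
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) return(c(s[1L], s[n]))
  width <- s[(k + 1L):n] - s[1L:(n - k)]
  j <- which.min(width)
  c(s[j], s[j + k])
}

#' ROPE decision rule
#'
#' `practically_zero` iff the HDI is entirely inside the ROPE;
#' `meaningfully_nonzero` iff they do not overlap; `undecided` otherwise.
#'
#' @param hdi_interval numeric `c(lower, upper)` (e.g. from [hdi()]).
#' @param rope an `hs_rope` or numeric `c(lower, upper)`.
#' @return one of `"practically_zero"`, `"meaningfully_nonzero"`,
#'   `"undecided"`.
#' @export
rope_decision <- function(hdi_interval, rope) {
  if (inherits(rope, "hs_rope")) rope <- c(rope$lower, rope$upper)
  stopifnot(length(hdi_interval) == 2L, length(rope) == 2L,
            hdi_interval[1] <= hdi_interval[2], rope[1] <= rope[2])
  if (hdi_interval[1] >= rope[1] && hdi_interval[2] <= rope[2]) {
    "practically_zero"
  } else if (hdi_interval[2] < rope[1] || hdi_interval[1] > rope[2]) {
    "meaningfully_nonzero"
  } else {
    "undecided"
  }
}

#' ROPE assessment of the belief-model positivity/accuracy hyperparameters
#'
#' Convenience wrapper reproducing the hyperparameter decision analysis:
#' builds the ROPE from the pooled standard deviation of the quantified
#' updates, takes the 95% HDI of `mu_k_acc` and (full model) `mu_k_pos`
#' draws, and applies the decision rule.  Individual point-estimate
#' histograms against the same ROPEs are available from the returned pieces.
#'
#' @param fit a belief-model `hs_fit`.
#' @param data the fitted dataset (for `sd_dv`).
#' @param mass HDI mass.
#' @return data.frame: parameter, HDI bounds, ROPE bounds, decision.
#' @export
rope_assessment <- function(fit, data, mass = 0.95) {
  stopifnot(fit$experiment == 2L)
  if (!"update" %in% names(data)) {
    data$update <- quantify_update(data$rating, data$dir_prediction)
  }
  sd_dv <- sd(data$update)
  m <- as.matrix(fit)
  rows <- list()
  spec <- list(mu_k_acc = "accuracy", mu_k_pos = "positivity")
  for (par in names(spec)) {
    if (!par %in% colnames(m)) next
    h <- hdi(m[, par], mass)
    rp <- rope_interval(spec[[par]], sd_dv)
    rows[[par]] <- data.frame(parameter = par, hdi_lower = h[1], hdi_upper = h[2],
                              rope_lower = rp$lower, rope_upper = rp$upper,
                              sd_dv = sd_dv,
                              decision = rope_decision(h, rp))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
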