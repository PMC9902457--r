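# Synthetic cohorts with the statistical structure the analyses assume,
# standing in for behavioural data that are available only on request.
# Default generating hyperparameters qualitatively mirror the reported
# findings (accuracy weight > positivity weight > 0; win-direction asymmetry
# k_sym > 1) and are documented as illustrative, not estimates.

#' Default generating hyperparameters for a model
#'
#' @param model model id.
#' @return named list of group-level locations/scales (and, for choice
#'   models, the truncated-Normal inverse-temperature hyperparameters).
#' @export
default_hypers <- function(model) {
  model <- match.arg(model, c(CHOICE_MODELS, BELIEF_MODELS))
  base_choice <- list(mu_beta = 2, sigma_beta = 1)
  switch(model,
    acc_pos  = c(list(mu_k_acc = 2, sigma_k_acc = 1,
                      mu_k_pos = 0.7, sigma_k_pos = 0.7), base_choice),
    acc_only = c(list(mu_k_acc = 2, sigma_k_acc = 1), base_choice),
    pos_only = c(list(mu_k_pos = 2, sigma_k_pos = 1), base_choice),
    tiebreak = c(list(mu_k_acc = 2, sigma_k_acc = 1,
                      mu_k_pos = 1.5, sigma_k_pos = 0.7), base_choice),
    full     = list(mu_k_cons = 5, sigma_k_cons = 2,
                    mu_k_acc = 4, sigma_k_acc = 1.5,
                    mu_k_pos = 1, sigma_k_pos = 0.5,
                    mu_k_sym = 1.5, sigma_k_sym = 0.25),
    no_pos   = list(mu_k_cons = 5, sigma_k_cons = 2,
                    mu_k_acc = 4, sigma_k_acc = 1.5,
                    mu_k_sym = 1.5, sigma_k_sym = 0.25))
}

#' Specify a synthetic cohort
#'
#' @param n_participants cohort size (>= 1).
#' @param model generating model id (fixes the experiment).
#' @param hypers generating hyperparameters ([default_hypers()] by default).
#' @param random_responder_fraction fraction of participants whose inverse
#'   temperature is forced to 0 (choice models only).
#' @param seed master seed; per-participant streams are fanned out from it.
#' @return object of class `hs_cohort_spec`.
#' @export
cohort_spec <- function(n_participants, model = "acc_pos",
                        hypers = default_hypers(model),
                        random_responder_fraction = 0, seed = 1L) {
  model <- match.arg(model, c(CHOICE_MODELS, BELIEF_MODELS))
  stopifnot(n_participants >= 1,
            random_responder_fraction >= 0, random_responder_fraction <= 1)
  structure(list(n_participants = as.integer(n_participants), model = model,
                 experiment = model_experiment(model), hypers = hypers,
                 random_responder_fraction = random_responder_fraction,
                 seed = seed), class = "hs_cohort_spec")
}

#' Draw individual participant parameters from the group distributions
#'
#' Weights are Normal draws at the stated hyperparameter values; the inverse
#' temperature is a truncated Normal on \[0, 5\]; `sigma_u` (belief models)
#' is Gamma(1, 0.5) unless the spec's hypers fix `sigma_u` directly.
#'
#' @param spec an [cohort_spec()] object.
#' @return data.frame, one row per participant, with a `is_random_responder`
#'   flag for choice cohorts.
#' @export
draw_participants <- function(spec) {
  h <- spec$hypers
  n <- spec$n_participants
  f <- model_features(spec$model)
  with_seed(spec$seed, {
    if (spec$experiment == 1L) {
      out <- data.frame(participant_id = seq_len(n))
      out$k_acc <- if (isTRUE(f$has_acc)) rnorm(n, h$mu_k_acc, h$sigma_k_acc) else 0
      out$k_pos <- if (isTRUE(f$has_pos)) rnorm(n, h$mu_k_pos, h$sigma_k_pos) else 0
      out$beta <- rtnorm(n, h$mu_beta, h$sigma_beta, 0, 5)
      n_rand <- round(spec$random_responder_fraction * n)
      out$is_random_responder <- seq_len(n) %in% sample.int(n, n_rand)
      out$beta[out$is_random_responder] <- 0
    } else {
      out <- data.frame(participant_id = seq_len(n))
      out$k_cons <- rnorm(n, h$mu_k_cons, h$sigma_k_cons)
      out$k_acc <- rnorm(n, h$mu_k_acc, h$sigma_k_acc)
      out$k_pos <- if (isTRUE(f$has_pos)) rnorm(n, h$mu_k_pos, h$sigma_k_pos) else 0
      out$k_sym <- rnorm(n, h$mu_k_sym, h$sigma_k_sym)
      out$sigma_u <- if (!is.null(h$sigma_u)) rep(h$sigma_u, n) else rgamma(n, 1, rate = 0.5)
    }
    out
  })
}

#' Generate a complete Experiment-1 dataset
#'
#' Per participant: an independently randomized 4-block schedule over the 16
#' default combinations, softmax choices from the generating model, an
#' own-lottery prediction from the chosen psychic (`P(win) = n_pos/5`), and
#' block-level win estimates plus confidence ratings.  The estimate and
#' confidence generators are *plumbing only* (a simple anchoring model on the
#' number of shown "win" predictions); they exercise the end-to-end pipeline
#' and are not part of the behavioural models.
#'
#' @param spec an [cohort_spec()] for a choice model.
#' @param combos combination table (default [default_exp1_combos()]).
#' @param n_blocks number of blocks.
#' @return trial-level data.frame with `chose_a`, `shown_prediction`,
#'   `win_estimate`, `confidence`; the drawn participant parameters sit in
#'   the `params` attribute.
#' @export
generate_exp1 <- function(spec, combos = default_exp1_combos(), n_blocks = 4L) {
  stopifnot(spec$experiment == 1L)
  params <- draw_participants(spec)
  datasets <- lapply(seq_len(spec$n_participants), function(i) {
    ps <- child_seed(spec$seed, 7L * i)
    sched <- build_exp1_schedule(combos, n_blocks, seed = ps,
                                 participant_id = params$participant_id[i])
    dat <- simulate_choices(spec$model, params[i, , drop = FALSE], sched,
                            seed = child_seed(ps, 1L))
    # block-level belief plumbing: estimates anchored between the shown wins
    # and the 50% base rate; confidence increasing in shown wins
    with_seed(child_seed(ps, 2L), {
      shown <- tapply(dat$shown_prediction, dat$block, sum)
      n_per_block <- as.integer(table(dat$block))
      est <- round(0.6 * shown + 0.4 * n_per_block / 2 + rnorm(length(shown), 0, 1.5))
      est <- pmin(pmax(est, 0), n_per_block)
      conf <- pmin(pmax(40 + 3 * shown + rnorm(length(shown), 0, 10), 0), 100)
      dat$win_estimate <- est[as.character(dat$block)]
      dat$confidence <- conf[as.character(dat$block)]
    })
    dat
  })
  out <- do.call(rbind, datasets)
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "spec") <- spec
  out
}

#' Generate a complete Experiment-2 dataset
#'
#' Balanced prediction-direction schedules and ratings from the generating
#' belief model; updates are pre-quantified.  Covariates are centered over
#' the full cohort schedule before simulation.
#'
#' @param spec an [cohort_spec()] for a belief model.
#' @param combos combination table (default [default_exp2_combos()]).
#' @return trial-level data.frame with `rating` and `update`; participant
#'   parameters in the `params` attribute, clipping count in `n_clipped`.
#' @export
generate_exp2 <- function(spec, combos = default_exp2_combos()) {
  stopifnot(spec$experiment == 2L)
  params <- draw_participants(spec)
  scheds <- lapply(seq_len(spec$n_participants), function(i) {
    build_exp2_schedule(combos, seed = child_seed(spec$seed, 7L * i),
                        participant_id = params$participant_id[i])
  })
  sched <- do.call(rbind, scheds)
  sched <- center_covariates(sched)
  out <- simulate_ratings(spec$model, params, sched,
                          seed = child_seed(spec$seed, 3L))
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "spec") <- spec
  out
}
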