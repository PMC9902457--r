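# Experiment-1 information-source choice models: the value of a source is a
# linear combination of its (centered) accuracy and positivity counts, choices
# follow a softmax with participant-specific inverse temperature beta in [0,5].

CHOICE_MODELS <- c("acc_pos", "acc_only", "pos_only", "tiebreak")
BELIEF_MODELS <- c("full", "no_pos")

model_features <- function(model) {
  switch(model,
         acc_pos  = list(has_acc = TRUE,  has_pos = TRUE,  eq_gate = FALSE),
         acc_only = list(has_acc = TRUE,  has_pos = FALSE, eq_gate = FALSE),
         pos_only = list(has_acc = FALSE, has_pos = TRUE,  eq_gate = FALSE),
         tiebreak = list(has_acc = TRUE,  has_pos = TRUE,  eq_gate = TRUE),
         full     = list(has_pos = TRUE),
         no_pos   = list(has_pos = FALSE),
         stop("unknown model id: ", model))
}

model_experiment <- function(model) if (model %in% CHOICE_MODELS) 1L else 2L

#' Center design covariates
#'
#' Subtracts the dataset-wide mean accuracy and positivity, pooled over every
#' *presented* psychic (both psychics of every Experiment-1 trial; the single
#' psychic of every Experiment-2 trial), and records the offsets so raw values
#' stay recoverable.  Centered columns get a `_c` suffix.  Recentering a
#' table recomputes from the raw columns, so the operation is idempotent.
#'
#' Note that in the two-source softmax only value *differences* matter, so
#' centering leaves the choice likelihood unchanged; it does matter for the
#' belief-update models where absolute covariates enter the mean update.
#'
#' @param data schedule or dataset of either experiment.
#' @return `data` with `*_c` columns added and a `centering` attribute
#'   (list with `acc_offset`, `pos_offset`).
#' @export
center_covariates <- function(data) {
  if (nrow(data) == 0L) stop("cannot center an empty schedule")
  if ("n_acc_a" %in% names(data)) {
    acc0 <- mean(c(data$n_acc_a, data$n_acc_b))
    pos0 <- mean(c(data$n_pos_a, data$n_pos_b))
    data$n_acc_a_c <- data$n_acc_a - acc0
    data$n_acc_b_c <- data$n_acc_b - acc0
    data$n_pos_a_c <- data$n_pos_a - pos0
    data$n_pos_b_c <- data$n_pos_b - pos0
  } else {
    acc0 <- mean(data$n_acc)
    pos0 <- mean(data$n_pos)
    data$n_acc_c <- data$n_acc - acc0
    data$n_pos_c <- data$n_pos - pos0
  }
  attr(data, "centering") <- list(acc_offset = acc0, pos_offset = pos0)
  data
}

#' Value of an information source under a choice model
#'
#' `acc_pos`: `k_acc * n_acc_c + k_pos * n_pos_c`; `acc_only` and `pos_only`
#' drop one term; `tiebreak` gates the positivity term by the equal-accuracy
#' indicator `eq` (1 iff the two psychics of the trial are equally accurate).
#'
#' @param model one of `"acc_pos"`, `"acc_only"`, `"pos_only"`, `"tiebreak"`.
#' @param k_acc,k_pos participant weights.
#' @param n_acc_c,n_pos_c centered covariates of the source.
#' @param eq equal-accuracy indicator (tiebreak model only).
#' @return numeric source value(s).
#' @export
source_value <- function(model, k_acc, k_pos, n_acc_c, n_pos_c, eq = 0) {
  f <- model_features(match.arg(model, CHOICE_MODELS))
  v <- 0
  if (f$has_acc) v <- v + k_acc * n_acc_c
  if (f$has_pos) v <- v + k_pos * n_pos_c * (if (f$eq_gate) eq else 1)
  v
}

#' Softmax probability of choosing source X over source Y
#'
#' `exp(beta V(X)) / (exp(beta V(X)) + exp(beta V(Y)))`, computed through the
#' logistic of `beta * (V(X) - V(Y))` so it is stable for large magnitudes.
#'
#' @param v_x,v_y source values.
#' @param beta inverse temperature, must lie in \[0, 5\].
#' @return probability in (0, 1).
#' @export
choice_probability <- function(v_x, v_y, beta) {
  if (any(beta < 0 | beta > 5)) stop("beta must lie in [0, 5]")
  plogis(beta * (v_x - v_y))
}

resolve_params <- function(params, pid) {
  # `params`: data.frame keyed by participant_id, or a single-row list/df
  # recycled over participants. Returns a data.frame aligned with `pid`.
  if (is.list(params) && !is.data.frame(params)) params <- as.data.frame(params)
  if (!"participant_id" %in% names(params)) {
    if (nrow(params) != 1L) stop("`params` without participant_id must have one row")
    return(params[rep(1L, length(pid)), , drop = FALSE])
  }
  idx <- match(pid, params$participant_id)
  if (anyNA(idx)) stop("parameters missing for some participants")
  params[idx, , drop = FALSE]
}

choice_design <- function(model, data) {
  f <- model_features(model)
  eq <- as.integer(data$n_acc_a == data$n_acc_b)
  d_acc <- data$n_acc_a - data$n_acc_b     # centering cancels in differences
  d_pos <- (data$n_pos_a - data$n_pos_b) * (if (f$eq_gate) eq else 1)
  list(d_acc = d_acc, d_pos = d_pos, eq = eq, f = f)
}

#' Log-likelihood of observed choices
#'
#' @param model choice model id.
#' @param params per-participant parameters: data.frame with
#'   `participant_id`, `k_acc`, `k_pos`, `beta` (unused columns may be
#'   absent); a single row is recycled over participants.
#' @param data choice dataset with design columns and `chose_a` in \{0, 1\}.
#' @return list with `total` and the per-trial `pointwise` vector (kept for
#'   pointwise cross-validation downstream).
#' @export
choice_loglik <- function(model, params, data) {
  model <- match.arg(model, CHOICE_MODELS)
  if (!"chose_a" %in% names(data) || anyNA(data$chose_a)) {
    stop("dataset must carry an observed `chose_a` for every trial")
  }
  ds <- choice_design(model, data)
  pp <- resolve_params(params, data$participant_id)
  v <- 0
  if (ds$f$has_acc) v <- v + pp$k_acc * ds$d_acc
  if (ds$f$has_pos) v <- v + pp$k_pos * ds$d_pos
  if (any(pp$beta < 0 | pp$beta > 5)) stop("beta must lie in [0, 5]")
  p <- plogis(pp$beta * v)
  pw <- dbinom(data$chose_a, 1L, p, log = TRUE)
  list(total = sum(pw), pointwise = pw)
}

#' Simulate choices from a choice model
#'
#' Generative counterpart of the softmax likelihood: Bernoulli draws per
#' trial, plus the chosen psychic's own-lottery prediction with
#' `P(win) = n_pos/5` (via [sample_own_prediction()]).
#'
#' @param model choice model id.
#' @param params per-participant parameter table (see [choice_loglik()]).
#' @param schedule Experiment-1 schedule (any number of participants).
#' @param seed optional seed.
#' @return the schedule with `chose_a` and `shown_prediction` columns.
#' @export
simulate_choices <- function(model, params, schedule, seed = NULL) {
  model <- match.arg(model, CHOICE_MODELS)
  ds <- choice_design(model, schedule)
  pp <- resolve_params(params, schedule$participant_id)
  v <- 0
  if (ds$f$has_acc) v <- v + pp$k_acc * ds$d_acc
  if (ds$f$has_pos) v <- v + pp$k_pos * ds$d_pos
  p <- plogis(pp$beta * v)
  with_seed(seed, {
    schedule$chose_a <- rbinom(nrow(schedule), 1L, p)
    n_pos_chosen <- ifelse(schedule$chose_a == 1L, schedule$n_pos_a, schedule$n_pos_b)
    schedule$shown_prediction <- sample_own_prediction(n_pos_chosen)
    schedule
  })
}
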