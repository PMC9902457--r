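# Experiment-2 belief-update quantification and the Gaussian update models.
#
# A belief rating r in [0, 100] around the 50-point indifference level is
# turned into a signed update U toward the direction of the psychic's
# own-lottery prediction; the mean update is linear in the (centered) source
# covariates and multiplied by an asymmetry factor k_sym on win-direction
# trials, capturing optimism bias confounded with asymmetric updating.

#' Quantify a belief update
#'
#' `U = rating - 50` when the psychic predicted a win (`dir = 1`), and
#' `U = 50 - rating` when it predicted a loss, so positive updates always
#' point in the direction of the prediction.  A loss prediction followed by a
#' rating of 10 is a 40-point update; a rating of 60 is a -10-point update.
#'
#' @param rating belief rating(s) on the 0-100 scale.
#' @param dir binary prediction direction(s), 1 = win predicted.
#' @return signed update(s) in rating points, in \[-50, 50\].
#' @export
quantify_update <- function(rating, dir) {
  if (any(rating < 0 | rating > 100, na.rm = FALSE) || anyNA(rating)) {
    stop("ratings must lie in [0, 100]")
  }
  stopifnot(all(dir %in% c(0, 1)))
  ifelse(dir == 1, rating - 50, 50 - rating)
}

#' Mean belief update under a belief model
#'
#' Full model: `(k_cons + k_acc * n_acc_c + k_pos * n_pos_c) *
#' (1 + (k_sym - 1) * dir)`; the no-positivity model drops the `k_pos` term.
#' The multiplier equals 1 on loss-prediction trials and `k_sym` on
#' win-prediction trials.
#'
#' @param model `"full"` or `"no_pos"`.
#' @param k_cons,k_acc,k_pos,k_sym participant parameters.
#' @param n_acc_c,n_pos_c centered covariates.
#' @param dir binary prediction direction.
#' @return mean update(s) in rating points.
#' @export
predict_mean_update <- function(model, k_cons, k_acc, k_pos = 0, k_sym = 1,
                                n_acc_c = 0, n_pos_c = 0, dir = 0) {
  model <- match.arg(model, BELIEF_MODELS)
  lin <- k_cons + k_acc * n_acc_c +
    (if (model_features(model)$has_pos) k_pos * n_pos_c else 0)
  lin * (1 + (k_sym - 1) * dir)
}

belief_covariates <- function(data) {
  if (!all(c("n_acc_c", "n_pos_c") %in% names(data))) data <- center_covariates(data)
  data
}

#' Log-likelihood of observed belief updates
#'
#' Gaussian log-density of each quantified update at its model-implied mean
#' with participant residual scale `sigma_u`.
#'
#' @param model `"full"` or `"no_pos"`.
#' @param params per-participant parameters: `participant_id`, `k_cons`,
#'   `k_acc`, `k_pos` (full model), `k_sym`, `sigma_u`.
#' @param data Experiment-2 dataset carrying `update` (or `rating` from which
#'   it is quantified) and `dir_prediction`.
#' @return list with `total` and per-trial `pointwise` vector.
#' @export
belief_loglik <- function(model, params, data) {
  model <- match.arg(model, BELIEF_MODELS)
  data <- belief_covariates(data)
  if (!"update" %in% names(data)) {
    data$update <- quantify_update(data$rating, data$dir_prediction)
  }
  pp <- resolve_params(params, data$participant_id)
  if (any(pp$sigma_u <= 0)) stop("sigma_u must be positive")
  mu <- predict_mean_update(model, pp$k_cons, pp$k_acc,
                            if (model_features(model)$has_pos) pp$k_pos else 0,
                            pp$k_sym, data$n_acc_c, data$n_pos_c,
                            data$dir_prediction)
  pw <- dnorm(data$update, mu, pp$sigma_u, log = TRUE)
  list(total = sum(pw), pointwise = pw)
}

#' Simulate belief ratings from a belief model
#'
#' Draws `U ~ Normal(mu_U, sigma_u)`, maps it back to the rating scale
#' (`rating = 50 + U` after a win prediction, `50 - U` after a loss
#' prediction), clips to \[0, 100\] and re-quantifies the update from the
#' clipped rating; the number of clipping events is recorded in the
#' `n_clipped` attribute.  Covariates are centered over the supplied schedule.
#'
#' @param model `"full"` or `"no_pos"`.
#' @param params per-participant parameter table (see [belief_loglik()]).
#' @param schedule Experiment-2 schedule.
#' @param seed optional seed.
#' @return the schedule with `rating` and `update` columns.
#' @export
simulate_ratings <- function(model, params, schedule, seed = NULL) {
  model <- match.arg(model, BELIEF_MODELS)
  schedule <- belief_covariates(schedule)
  pp <- resolve_params(params, schedule$participant_id)
  mu <- predict_mean_update(model, pp$k_cons, pp$k_acc,
                            if (model_features(model)$has_pos) pp$k_pos else 0,
                            pp$k_sym, schedule$n_acc_c, schedule$n_pos_c,
                            schedule$dir_prediction)
  with_seed(seed, {
    u <- rnorm(nrow(schedule), mu, pp$sigma_u)
    rating <- ifelse(schedule$dir_prediction == 1, 50 + u, 50 - u)
    clipped <- rating < 0 | rating > 100
    rating <- pmin(pmax(rating, 0), 100)
    schedule$rating <- rating
    schedule$update <- quantify_update(rating, schedule$dir_prediction)
    attr(schedule, "n_clipped") <- sum(clipped)
    schedule
  })
}
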