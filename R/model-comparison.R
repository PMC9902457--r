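# Participant-wise cross-validated model comparison: pointwise log-likelihood
# matrices, leave-one-participant-out elpd (exact refits or truncated
# importance sampling over the full-data posterior), WAIC, Bayesian stacking
# weights, best-predictor proportions and posterior predictive checks.

rep_row <- function(x, s) matrix(x, nrow = s, ncol = length(x), byrow = TRUE)

#' Pointwise log-likelihood matrix
#'
#' Log-likelihood of every observation at every retained posterior draw,
#' using each draw's individual-level parameters.
#'
#' @param fit an `hs_fit`.
#' @param data dataset whose participants all appear in the fit.
#' @return list of class `hs_pointwise`: `ll` (draws x observations matrix)
#'   and `participant` (observation-to-participant map).
#' @export
pointwise_loglik <- function(fit, data) {
  if (nrow(data) == 0L) stop("empty dataset")
  pid <- match(data$participant_id, fit$participants)
  if (anyNA(pid)) stop("dataset/posterior mismatch: unknown participants")
  s <- dim(fit$draws)[1] * dim(fit$draws)[2]
  if (fit$model %in% CHOICE_MODELS) {
    ds <- choice_design(fit$model, data)
    v <- matrix(0, s, nrow(data))
    kA <- indiv_draws(fit, "k_acc"); kP <- indiv_draws(fit, "k_pos")
    if (!is.null(kA)) v <- v + kA[, pid, drop = FALSE] * rep_row(ds$d_acc, s)
    if (!is.null(kP)) v <- v + kP[, pid, drop = FALSE] * rep_row(ds$d_pos, s)
    sc <- indiv_draws(fit, "beta")[, pid, drop = FALSE] * v
    y <- rep_row(data$chose_a, s)
    ll <- ifelse(y == 1, plogis(sc, log.p = TRUE), plogis(-sc, log.p = TRUE))
  } else {
    data <- apply_fit_centering(fit, data)
    if (!"update" %in% names(data)) {
      data$update <- quantify_update(data$rating, data$dir_prediction)
    }
    kC <- indiv_draws(fit, "k_cons")[, pid, drop = FALSE]
    kA <- indiv_draws(fit, "k_acc")[, pid, drop = FALSE]
    kP <- indiv_draws(fit, "k_pos")
    kS <- indiv_draws(fit, "k_sym")[, pid, drop = FALSE]
    sU <- indiv_draws(fit, "sigma_u")[, pid, drop = FALSE]
    lin <- kC + kA * rep_row(data$n_acc_c, s)
    if (!is.null(kP)) lin <- lin + kP[, pid, drop = FALSE] * rep_row(data$n_pos_c, s)
    mu <- lin * (1 + (kS - 1) * rep_row(data$dir_prediction, s))
    ll <- dnorm(rep_row(data$update, s), mu, sU, log = TRUE)
  }
  structure(list(ll = ll, participant = data$participant_id),
            class = "hs_pointwise")
}

# center a belief dataset with the offsets stored in the fit (so held-out
# data live on the same covariate scale the model was estimated on)
apply_fit_centering <- function(fit, data) {
  if (is.null(fit$centering)) return(belief_covariates(data))
  data$n_acc_c <- data$n_acc - fit$centering$acc_offset
  data$n_pos_c <- data$n_pos - fit$centering$pos_offset
  data
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 (lppd - p_waic)` on the deviance scale (smaller is better),
#' with `lppd = sum_n log mean_s p(y_n | theta_s)` and `p_waic = sum_n
#' var_s log p(y_n | theta_s)`.
#'
#' @param x an `hs_pointwise` object or a draws x observations log-likelihood
#'   matrix (needs at least 2 draws).
#' @return list: `waic`, `lppd`, `p_waic`, `se` (per-observation convention),
#'   and the per-observation `pointwise` contributions.
#' @export
waic <- function(x) {
  ll <- if (inherits(x, "hs_pointwise")) x$ll else as.matrix(x)
  if (nrow(ll) < 2L) stop("WAIC needs at least 2 posterior draws")
  lme <- apply(ll, 2, logmeanexp)
  pw_p <- apply(ll, 2, var)
  pointwise <- -2 * (lme - pw_p)
  n <- length(pointwise)
  list(waic = sum(pointwise), lppd = sum(lme), p_waic = sum(pw_p),
       se = sqrt(n * var(pointwise)), pointwise = pointwise)
}

split_by_participant <- function(data) {
  split(seq_len(nrow(data)), data$participant_id)[
    as.character(unique(data$participant_id))]
}

choice_marg_inputs <- function(model, data_i) {
  ds <- choice_design(model, data_i)
  list(d_acc = as.double(ds$d_acc), d_pos = as.double(ds$d_pos),
       y = as.integer(data_i$chose_a))
}

#' Leave-one-participant-out expected log predictive density
#'
#' For each held-out participant the predictive density marginalizes the
#' individual parameters over the group-level distribution (`inner_draws`
#' Monte-Carlo draws per posterior draw), matching prediction for a *new*
#' participant.  `method = "exact_refit"` refits the model without the
#' participant; `method = "tis"` reuses the full-data posterior with
#' truncated importance sampling, capping raw weights at
#' `mean(weight) * sqrt(S)`.
#'
#' @param fit full-data `hs_fit`.
#' @param data the dataset the fit was estimated on (>= 2 participants).
#' @param method `"tis"` (default) or `"exact_refit"`.
#' @param inner_draws Monte-Carlo draws for the new-participant marginal.
#' @param refit_config sampler config for the per-fold refits (defaults to
#'   the fit's own config).
#' @param seed optional seed for the marginalization draws.
#' @return named vector of per-participant elpd contributions with
#'   attributes `total`, `se` (participant-level standard error of the sum),
#'   `mc_se` (per-participant Monte-Carlo error) and `method`.
#' @export
participant_elpd <- function(fit, data, method = c("tis", "exact_refit"),
                             inner_draws = 100L, refit_config = NULL,
                             seed = NULL) {
  method <- match.arg(method)
  idx <- split_by_participant(data)
  if (length(idx) < 2L) stop("no training data for the fold: need >= 2 participants")
  ids <- names(idx)
  elpd <- mc_se <- setNames(numeric(length(idx)), ids)

  marg <- function(afit, data_i) {
    hy <- hyper_draw_matrix(afit)
    if (afit$model %in% CHOICE_MODELS) {
      mi <- choice_marg_inputs(afit$model, data_i)
      cpp_choice_marg_ll(hy, mi$d_acc, mi$d_pos, mi$y, as.integer(inner_draws),
                         model_features(afit$model)$has_acc,
                         model_features(afit$model)$has_pos)
    } else {
      di <- apply_fit_centering(afit, data_i)
      if (!"update" %in% names(di)) di$update <- quantify_update(di$rating, di$dir_prediction)
      cpp_belief_marg_ll(hy, as.double(di$n_acc_c), as.double(di$n_pos_c),
                         as.integer(di$dir_prediction), as.double(di$update),
                         as.integer(inner_draws),
                         model_features(afit$model)$has_pos)
    }
  }

  # Monte-Carlo error of an elpd estimate: the posterior draws behind logm
  # are autocorrelated, so the naive 1/sqrt(S) rate is scaled by the
  # effective sample size of the integrand sequence (per chain).
  autocorr_factor <- function(x, n_chains) {
    s <- length(x)
    iters <- s %/% n_chains
    if (iters < 16L) return(1)
    e <- ess_basic(matrix(x[seq_len(iters * n_chains)], iters, n_chains))
    if (!is.finite(e) || e <= 0) return(1)
    sqrt(max(1, s / e))
  }

  with_seed(seed, {
    if (method == "tis") {
      for (k in seq_along(idx)) {
        data_i <- data[idx[[k]], , drop = FALSE]
        logm <- marg(fit, data_i)
        s <- length(logm)
        logr <- -logm
        logcap <- logmeanexp(logr) + 0.5 * log(s)
        logw <- pmin(logr, logcap)
        elpd[k] <- logsumexp(logw + logm) - logsumexp(logw)
        wn <- exp(logw - logsumexp(logw))
        pt <- exp(logm - max(logm))
        rt <- sum(wn * pt)
        mc_se[k] <- sqrt(sum(wn^2 * (pt - rt)^2)) / rt *
          autocorr_factor(logm, fit$config$chains)
      }
    } else {
      cfg <- refit_config %||% fit$config
      for (k in seq_along(idx)) {
        keep <- data$participant_id != unique(data$participant_id)[k]
        refit <- suppressWarnings(fit_hierarchical(fit$model,
                                                   data[keep, , drop = FALSE],
                                                   cfg))
        logm <- marg(refit, data[idx[[k]], , drop = FALSE])
        elpd[k] <- logmeanexp(logm)
        pt <- exp(logm - max(logm))
        mc_se[k] <- sd(pt) / (mean(pt) * sqrt(length(pt))) *
          autocorr_factor(logm, cfg$chains)
      }
    }
  })
  attr(elpd, "total") <- sum(elpd)
  attr(elpd, "se") <- sqrt(length(elpd) * var(as.numeric(elpd)))
  attr(elpd, "mc_se") <- mc_se
  attr(elpd, "method") <- method
  elpd
}

stacking_objective <- function(w, elpd_mat) {
  shift <- apply(elpd_mat, 1, max)
  sum(log(exp(elpd_mat - shift) %*% w)) + sum(shift)
}

#' Bayesian stacking weights
#'
#' Simplex weights maximizing the summed log predictive density of the
#' weighted model mixture, `sum_i log sum_k w_k exp(elpd_ik)` — a concave
#' problem solved by multiplicative (EM) updates from a uniform start, so two
#' identical models receive equal weight by convention.
#'
#' @param elpd_mat participants x models matrix of elpd contributions
#'   (finite entries required).
#' @param tol convergence tolerance on the weights.
#' @param max_iter iteration cap.
#' @return named weight vector on the simplex.
#' @export
stacking_weights <- function(elpd_mat, tol = 1e-10, max_iter = 100000L) {
  elpd_mat <- as.matrix(elpd_mat)
  if (any(!is.finite(elpd_mat))) stop("non-finite elpd entries")
  k <- ncol(elpd_mat)
  nms <- colnames(elpd_mat) %||% paste0("model", seq_len(k))
  if (k == 1L) return(setNames(1, nms))
  p <- exp(elpd_mat - apply(elpd_mat, 1, max))
  w <- rep(1 / k, k)
  for (it in seq_len(max_iter)) {
    denom <- drop(p %*% w)
    w_new <- colMeans(p * rep(w, each = nrow(p)) / denom)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  setNames(w, nms)
}

#' Proportion of participants best predicted by each model
#'
#' Argmax of each participant's elpd row; exact ties are split equally.
#'
#' @param elpd_mat participants x models elpd matrix.
#' @return named proportions summing to 1.
#' @export
best_model_proportions <- function(elpd_mat) {
  elpd_mat <- as.matrix(elpd_mat)
  k <- ncol(elpd_mat)
  nms <- colnames(elpd_mat) %||% paste0("model", seq_len(k))
  share <- matrix(0, nrow(elpd_mat), k)
  for (i in seq_len(nrow(elpd_mat))) {
    win <- which(elpd_mat[i, ] == max(elpd_mat[i, ]))
    share[i, win] <- 1 / length(win)
  }
  setNames(colSums(share) / nrow(elpd_mat), nms)
}

#' Fit and compare a set of models on one dataset
#'
#' Produces the usual comparison table: summed leave-one-participant-out
#' elpd with its participant-level standard error, the difference from the
#' best model, WAIC, stacking weights and best-predictor proportions.
#'
#' @param data dataset of one experiment.
#' @param models character vector of model ids (all of the same experiment).
#' @param config sampler config used for every fit.
#' @param method elpd method, `"tis"` or `"exact_refit"`.
#' @param inner_draws marginalization draws (see [participant_elpd()]).
#' @param fits optional pre-computed named list of `hs_fit` objects.
#' @param seed optional seed for the elpd marginalization.
#' @return object of class `hs_comparison`.
#' @export
compare_models <- function(data, models, config = sampler_config(),
                           method = "tis", inner_draws = 100L, fits = NULL,
                           seed = NULL) {
  if (is.null(fits)) {
    fits <- setNames(lapply(models, function(m) {
      suppressWarnings(fit_hierarchical(m, data, config))
    }), models)
  }
  elpd_mat <- sapply(models, function(m) {
    as.numeric(participant_elpd(fits[[m]], data, method = method,
                                inner_draws = inner_draws,
                                seed = child_seed(seed, match(m, models))))
  })
  rownames(elpd_mat) <- as.character(unique(data$participant_id))
  waics <- lapply(models, function(m) waic(pointwise_loglik(fits[[m]], data)))
  totals <- colSums(elpd_mat)
  best <- which.max(totals)
  delta <- totals - totals[best]
  delta_se <- vapply(seq_along(models), function(k) {
    d <- elpd_mat[, k] - elpd_mat[, best]
    sqrt(nrow(elpd_mat) * var(d))
  }, numeric(1))
  structure(list(
    models = models,
    elpd = elpd_mat,
    elpd_total = totals,
    elpd_se = apply(elpd_mat, 2, function(x) sqrt(length(x) * var(x))),
    delta_elpd = delta, delta_se = delta_se,
    waic = vapply(waics, `[[`, numeric(1), "waic"),
    waic_se = vapply(waics, `[[`, numeric(1), "se"),
    stacking = stacking_weights(elpd_mat),
    prop_best = best_model_proportions(elpd_mat),
    method = method, fits = fits), class = "hs_comparison")
}

#' @export
print.hs_comparison <- function(x, ...) {
  tab <- data.frame(
    model = x$models,
    elpd = sprintf("%.1f (%.1f)", x$elpd_total, x$elpd_se),
    delta_elpd = ifelse(x$delta_elpd == 0, "-",
                        sprintf("%.1f (%.1f)", x$delta_elpd, x$delta_se)),
    waic = sprintf("%.2f (%.2f)", x$waic, x$waic_se),
    weight = sprintf("%.3f", x$stacking),
    prop_best = sprintf("%.3f", x$prop_best))
  cat(sprintf("Model comparison (%s leave-one-participant-out elpd)\n", x$method))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Posterior predictive check
#'
#' Simulates replicated datasets from retained posterior draws (individual
#' parameters of each draw) on the observed design and compares observed
#' summary statistics with their replicated central 95% interval.  For choice
#' data the statistics are the positivity preference on equal-accuracy trials
#' and the accuracy preference on unequal-accuracy trials; for belief data,
#' mean updates by prediction direction and by source accuracy.
#'
#' @param fit an `hs_fit`.
#' @param data the observed dataset.
#' @param n_rep number of replicated datasets.
#' @param seed optional seed.
#' @return data.frame: statistic, observed value, replicated mean and
#'   central 95% bounds, and whether the observed value is inside.
#' @export
posterior_predictive_check <- function(fit, data, n_rep = 100L, seed = NULL) {
  if (nrow(data) == 0L) stop("empty dataset")
  pid <- match(data$participant_id, fit$participants)
  if (anyNA(pid)) stop("dataset/posterior mismatch: unknown participants")
  s_tot <- dim(fit$draws)[1] * dim(fit$draws)[2]

  if (fit$model %in% CHOICE_MODELS) {
    ds <- choice_design(fit$model, data)
    eq <- ds$eq == 1L
    more_pos_a <- data$n_pos_a > data$n_pos_b
    more_acc_a <- data$n_acc_a > data$n_acc_b
    stat_fun <- function(chose) {
      c(pos_pref_equal_acc = mean(ifelse(more_pos_a[eq], chose[eq], 1 - chose[eq])),
        acc_pref_unequal  = mean(ifelse(more_acc_a[!eq], chose[!eq], 1 - chose[!eq])))
    }
    obs <- stat_fun(data$chose_a)
    kA <- indiv_draws(fit, "k_acc"); kP <- indiv_draws(fit, "k_pos")
    beta <- indiv_draws(fit, "beta")
    rep_stats <- with_seed(seed, {
      draws_use <- sample.int(s_tot, n_rep, replace = n_rep > s_tot)
      t(sapply(draws_use, function(s) {
        v <- 0
        if (!is.null(kA)) v <- v + kA[s, pid] * ds$d_acc
        if (!is.null(kP)) v <- v + kP[s, pid] * ds$d_pos
        stat_fun(rbinom(nrow(data), 1L, plogis(beta[s, pid] * v)))
      }))
    })
  } else {
    data <- apply_fit_centering(fit, data)
    if (!"update" %in% names(data)) data$update <- quantify_update(data$rating, data$dir_prediction)
    hi_acc <- data$n_acc >= stats::median(unique(data$n_acc))
    stat_fun <- function(u) {
      c(mean_update_win_pred  = mean(u[data$dir_prediction == 1]),
        mean_update_loss_pred = mean(u[data$dir_prediction == 0]),
        mean_update_high_acc  = mean(u[hi_acc]),
        mean_update_low_acc   = mean(u[!hi_acc]))
    }
    obs <- stat_fun(data$update)
    kC <- indiv_draws(fit, "k_cons"); kA <- indiv_draws(fit, "k_acc")
    kP <- indiv_draws(fit, "k_pos"); kS <- indiv_draws(fit, "k_sym")
    sU <- indiv_draws(fit, "sigma_u")
    rep_stats <- with_seed(seed, {
      draws_use <- sample.int(s_tot, n_rep, replace = n_rep > s_tot)
      t(sapply(draws_use, function(s) {
        lin <- kC[s, pid] + kA[s, pid] * data$n_acc_c
        if (!is.null(kP)) lin <- lin + kP[s, pid] * data$n_pos_c
        mu <- lin * (1 + (kS[s, pid] - 1) * data$dir_prediction)
        stat_fun(rnorm(nrow(data), mu, sU[s, pid]))
      }))
    })
  }
  lo <- apply(rep_stats, 2, quantile, 0.025)
  hi <- apply(rep_stats, 2, quantile, 0.975)
  data.frame(statistic = names(obs), observed = unname(obs),
             rep_mean = unname(colMeans(rep_stats)),
             rep_lower = unname(lo), rep_upper = unname(hi),
             inside = unname(obs >= lo & obs <= hi))
}
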