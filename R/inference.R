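# Hierarchical Bayesian fitting of the six models with the printed priors:
# mu_kAcc, mu_kPos, mu_kCons, log(mu_kSym) ~ Normal(0, 1); mu_beta ~
# Normal(0, 2); every group scale and sigma_U ~ Gamma(1, 0.5); individual
# weights Normal(mu, sigma) (non-centered); beta Normal(mu, sigma) truncated
# to [0, 5] via a logistic transform with proper normalization.

#' Sampler configuration
#'
#' Defaults are the original protocol's scale (4 chains, 1500 warm-up
#' iterations, 5000 retained draws per chain); test-scale configurations are
#' routinely used in the test-suite and recovery studies.
#'
#' @param chains number of chains (>= 2 needed for convergence diagnostics).
#' @param warmup,draws warm-up and retained iterations per chain.
#' @param seed master seed; per-chain seeds are derived from it.
#' @param rhat_threshold split-R-hat pass threshold (default 1.01).
#' @param max_divergent divergence tolerance for the pass flag.
#' @param adapt_delta dual-averaging target acceptance.
#' @param L leapfrog step-count range.
#' @return an object of class `hs_config`.
#' @export
sampler_config <- function(chains = 4L, warmup = 1500L, draws = 5000L,
                           seed = 1L, rhat_threshold = 1.01,
                           max_divergent = 0L, adapt_delta = 0.9,
                           L = c(32L, 64L)) {
  stopifnot(chains >= 1, warmup >= 0, draws > 0)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = seed,
                 rhat_threshold = rhat_threshold,
                 max_divergent = max_divergent,
                 adapt_delta = adapt_delta, L = L),
            class = "hs_config")
}

choice_layout <- function(n, f) {
  off <- 0L; lay <- list()
  if (f$has_acc) { lay$zA <- off + seq_len(n); off <- off + n }
  if (f$has_pos) { lay$zP <- off + seq_len(n); off <- off + n }
  lay$braw <- off + seq_len(n); off <- off + n
  if (f$has_acc) { lay$muA <- off + 1L; lay$lsA <- off + 2L; off <- off + 2L }
  if (f$has_pos) { lay$muP <- off + 1L; lay$lsP <- off + 2L; off <- off + 2L }
  lay$muB <- off + 1L; lay$lsB <- off + 2L
  lay$dim <- off + 2L
  lay
}

belief_layout <- function(n, f) {
  off <- 0L; lay <- list()
  lay$zC <- off + seq_len(n); off <- off + n
  lay$zA <- off + seq_len(n); off <- off + n
  if (f$has_pos) { lay$zP <- off + seq_len(n); off <- off + n }
  lay$zS <- off + seq_len(n); off <- off + n
  lay$lsU <- off + seq_len(n); off <- off + n
  lay$muC <- off + 1L; lay$lsC <- off + 2L; off <- off + 2L
  lay$muA <- off + 1L; lay$lsA <- off + 2L; off <- off + 2L
  if (f$has_pos) { lay$muP <- off + 1L; lay$lsP <- off + 2L; off <- off + 2L }
  lay$etaS <- off + 1L; lay$lsS <- off + 2L
  lay$dim <- off + 2L
  lay
}

# raw chain draws -> natural-scale named matrix
transform_choice_draws <- function(raw, lay, f, n) {
  cols <- list()
  if (f$has_acc) {
    cols[[length(cols) + 1L]] <- raw[, lay$muA] + exp(raw[, lay$lsA]) * raw[, lay$zA, drop = FALSE]
  }
  if (f$has_pos) {
    cols[[length(cols) + 1L]] <- raw[, lay$muP] + exp(raw[, lay$lsP]) * raw[, lay$zP, drop = FALSE]
  }
  cols[[length(cols) + 1L]] <- 5 * plogis(raw[, lay$braw, drop = FALSE])
  hy <- cbind(
    if (f$has_acc) cbind(raw[, lay$muA], exp(raw[, lay$lsA])),
    if (f$has_pos) cbind(raw[, lay$muP], exp(raw[, lay$lsP])),
    raw[, lay$muB], exp(raw[, lay$lsB]))
  out <- do.call(cbind, c(cols, list(hy)))
  nm <- c(if (f$has_acc) sprintf("k_acc[%d]", seq_len(n)),
          if (f$has_pos) sprintf("k_pos[%d]", seq_len(n)),
          sprintf("beta[%d]", seq_len(n)),
          if (f$has_acc) c("mu_k_acc", "sigma_k_acc"),
          if (f$has_pos) c("mu_k_pos", "sigma_k_pos"),
          "mu_beta", "sigma_beta")
  colnames(out) <- nm
  out
}

transform_belief_draws <- function(raw, lay, f, n) {
  # the k-blocks are sampled centered, i.e. already on the natural scale
  mu_sym <- exp(raw[, lay$etaS])
  cols <- list(raw[, lay$zC, drop = FALSE], raw[, lay$zA, drop = FALSE])
  if (f$has_pos) cols[[3L]] <- raw[, lay$zP, drop = FALSE]
  cols[[length(cols) + 1L]] <- raw[, lay$zS, drop = FALSE]
  cols[[length(cols) + 1L]] <- exp(raw[, lay$lsU, drop = FALSE])
  hy <- cbind(raw[, lay$muC], exp(raw[, lay$lsC]),
              raw[, lay$muA], exp(raw[, lay$lsA]),
              if (f$has_pos) cbind(raw[, lay$muP], exp(raw[, lay$lsP])),
              mu_sym, exp(raw[, lay$lsS]))
  out <- do.call(cbind, c(cols, list(hy)))
  nm <- c(sprintf("k_cons[%d]", seq_len(n)),
          sprintf("k_acc[%d]", seq_len(n)),
          if (f$has_pos) sprintf("k_pos[%d]", seq_len(n)),
          sprintf("k_sym[%d]", seq_len(n)),
          sprintf("sigma_u[%d]", seq_len(n)),
          "mu_k_cons", "sigma_k_cons", "mu_k_acc", "sigma_k_acc",
          if (f$has_pos) c("mu_k_pos", "sigma_k_pos"),
          "mu_k_sym", "sigma_k_sym")
  colnames(out) <- nm
  out
}

#' Fit a hierarchical model by Hamiltonian Monte Carlo
#'
#' Samples the joint posterior of all individual-level parameters and group
#' hyperparameters for any of the four choice models (`"acc_pos"`,
#' `"acc_only"`, `"pos_only"`, `"tiebreak"`) or two belief models (`"full"`,
#' `"no_pos"`).  An empty dataset (zero rows, with `participants` supplied)
#' yields prior-only sampling.  Non-convergence (R-hat above threshold or
#' divergences beyond tolerance) is flagged in the stored diagnostics, never
#' silently accepted; a warning is emitted.
#'
#' @param model model id.
#' @param data trial-level dataset of the matching experiment.
#' @param config an [sampler_config()] object.
#' @param participants optional explicit participant-id vector (required when
#'   `data` has zero rows).
#' @return object of class `hs_fit`: `draws` is an iterations x chains x
#'   variables array on the natural scale (individual `k_*[i]`, `beta[i]`,
#'   `sigma_u[i]` and the group-level `mu_*` / `sigma_*`), plus per-chain
#'   divergence counts, the sampler config, the data fingerprint and the
#'   centering offsets used.
#' @export
fit_hierarchical <- function(model, data, config = sampler_config(),
                             participants = NULL) {
  model <- match.arg(model, c(CHOICE_MODELS, BELIEF_MODELS))
  f <- model_features(model)
  participants <- participants %||% unique(data$participant_id)
  n <- length(participants)
  if (n < 1L) stop("need at least one participant")
  centering <- NULL
  if (model %in% CHOICE_MODELS) {
    if (nrow(data) > 0L) {
      if (!"chose_a" %in% names(data)) stop("choice dataset must carry `chose_a`")
      ds <- choice_design(model, data)
      d_acc <- as.double(ds$d_acc); d_pos <- as.double(ds$d_pos)
      y <- as.integer(data$chose_a)
      pid0 <- match(data$participant_id, participants) - 1L
    } else {
      d_acc <- d_pos <- double(0); y <- pid0 <- integer(0)
    }
    lay <- choice_layout(n, f)
    lpg <- function(th) cpp_choice_lpgrad(th, d_acc, d_pos, y, pid0, n,
                                          f$has_acc, f$has_pos)
  } else {
    if (nrow(data) > 0L) {
      data <- belief_covariates(data)
      centering <- attr(data, "centering")
      if (!"update" %in% names(data)) {
        data$update <- quantify_update(data$rating, data$dir_prediction)
      }
      acc_c <- as.double(data$n_acc_c); pos_c <- as.double(data$n_pos_c)
      dir <- as.integer(data$dir_prediction); U <- as.double(data$update)
      pid0 <- match(data$participant_id, participants) - 1L
    } else {
      acc_c <- pos_c <- U <- double(0); dir <- pid0 <- integer(0)
    }
    lay <- belief_layout(n, f)
    lpg <- function(th) cpp_belief_lpgrad(th, acc_c, pos_c, dir, U, pid0, n,
                                          f$has_pos)
  }
  if (anyNA(pid0)) stop("data contain participants not listed in `participants`")

  chains <- lapply(seq_len(config$chains), function(cc) {
    init <- with_seed(child_seed(config$seed, 1000L + cc),
                      rnorm(lay$dim, 0, 0.1))
    hmc_chain(lpg, init, config$warmup, config$draws,
              seed = child_seed(config$seed, cc),
              control = list(adapt_delta = config$adapt_delta, L = config$L))
  })
  trans <- if (model %in% CHOICE_MODELS) {
    lapply(chains, function(ch) transform_choice_draws(ch$draws, lay, f, n))
  } else {
    lapply(chains, function(ch) transform_belief_draws(ch$draws, lay, f, n))
  }
  nv <- ncol(trans[[1L]])
  arr <- array(NA_real_, c(config$draws, config$chains, nv + 1L),
               dimnames = list(NULL, NULL, c(colnames(trans[[1L]]), "lp__")))
  for (cc in seq_along(trans)) {
    arr[, cc, seq_len(nv)] <- trans[[cc]]
    arr[, cc, nv + 1L] <- chains[[cc]]$lp
  }
  fit <- structure(list(
    model = model, experiment = model_experiment(model),
    participants = participants, n_participants = n,
    draws = arr,
    n_divergent = vapply(chains, `[[`, integer(1), "n_divergent"),
    accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
    config = config, centering = centering,
    data_fingerprint = fingerprint(data)), class = "hs_fit")
  if (config$chains >= 2L) {
    dg <- diagnostics(fit)
    fit$diagnostics <- dg
    if (!attr(dg, "pass")) {
      warning(sprintf("fit of '%s' flagged by diagnostics (max R-hat %.3f, %d divergent)",
                      model, max(dg$rhat, na.rm = TRUE), sum(fit$n_divergent)))
    }
  }
  fit
}

#' @export
print.hs_fit <- function(x, ...) {
  cat(sprintf("Hierarchical fit: model '%s' (experiment %d)\n", x$model, x$experiment))
  cat(sprintf("  %d participants; %d chains x %d draws (+%d warmup); %d divergent\n",
              x$n_participants, x$config$chains, x$config$draws,
              x$config$warmup, sum(x$n_divergent)))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  max split R-hat %.3f; min ESS %.0f\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                min(x$diagnostics$ess, na.rm = TRUE)))
  }
  invisible(x)
}

# All post-warmup draws as a (chains*iterations) x variables matrix.
#' @export
as.matrix.hs_fit <- function(x, ...) {
  d <- dim(x$draws)
  out <- matrix(aperm(x$draws, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(out) <- dimnames(x$draws)[[3]]
  out
}

# draws of one indexed family, S x n matrix (internal)
indiv_draws <- function(fit, param) {
  m <- as.matrix(fit)
  cols <- sprintf("%s[%d]", param, seq_len(fit$n_participants))
  if (!all(cols %in% colnames(m))) return(NULL)
  m[, cols, drop = FALSE]
}

hyper_draw_matrix <- function(fit) {
  m <- as.matrix(fit)
  grab <- function(nm) if (nm %in% colnames(m)) m[, nm] else rep(0, nrow(m))
  if (fit$model %in% CHOICE_MODELS) {
    cbind(grab("mu_k_acc"), pmax(grab("sigma_k_acc"), 1e-12),
          grab("mu_k_pos"), pmax(grab("sigma_k_pos"), 1e-12),
          grab("mu_beta"), pmax(grab("sigma_beta"), 1e-12))
  } else {
    cbind(grab("mu_k_cons"), pmax(grab("sigma_k_cons"), 1e-12),
          grab("mu_k_acc"), pmax(grab("sigma_k_acc"), 1e-12),
          grab("mu_k_pos"), pmax(grab("sigma_k_pos"), 1e-12),
          grab("mu_k_sym"), pmax(grab("sigma_k_sym"), 1e-12))
  }
}

#' Posterior point estimates
#'
#' Per-participant posterior means (or medians) of the individual-level
#' parameters — including the accuracy- and positivity-preference weights —
#' plus summaries of the group-level hyperparameters.
#'
#' @param fit an `hs_fit`.
#' @param stat `"mean"` (default) or `"median"`.
#' @return list of class `hs_estimates` with data.frames `individual`
#'   (one row per participant) and `hyper` (mean, sd, central 95% interval).
#' @export
point_estimates <- function(fit, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  fun <- if (stat == "mean") colMeans else function(m) apply(m, 2, median)
  fams <- if (fit$model %in% CHOICE_MODELS) {
    c("k_acc", "k_pos", "beta")
  } else {
    c("k_cons", "k_acc", "k_pos", "k_sym", "sigma_u")
  }
  ind <- data.frame(participant_id = fit$participants)
  for (fam in fams) {
    d <- indiv_draws(fit, fam)
    if (!is.null(d)) ind[[fam]] <- unname(fun(d))
  }
  m <- as.matrix(fit)
  hn <- grep("^(mu_|sigma_)", colnames(m), value = TRUE)
  hn <- setdiff(hn, sprintf("sigma_u[%d]", seq_len(fit$n_participants)))
  hy <- data.frame(parameter = hn,
                   estimate = unname(fun(m[, hn, drop = FALSE])),
                   sd = unname(apply(m[, hn, drop = FALSE], 2, sd)),
                   q2.5 = unname(apply(m[, hn, drop = FALSE], 2, quantile, 0.025)),
                   q97.5 = unname(apply(m[, hn, drop = FALSE], 2, quantile, 0.975)))
  structure(list(individual = ind, hyper = hy, stat = stat),
            class = "hs_estimates")
}

#' Split R-hat of one parameter
#'
#' Classic potential-scale-reduction computed after splitting each chain in
#' half, so within-chain drift also inflates the statistic.
#'
#' @param mat iterations x chains matrix of post-warm-up draws.
#' @return R-hat (NA when variance degenerates or fewer than 4 iterations).
#' @export
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sp <- do.call(cbind, lapply(seq_len(ncol(mat)), function(cc) {
    cbind(mat[seq_len(half), cc], mat[half + seq_len(half), cc])
  }))
  w <- mean(apply(sp, 2, var))
  if (!is.finite(w) || w <= 0) return(NA_real_)
  b <- half * var(colMeans(sp))
  vp <- (half - 1) / half * w + b / half
  sqrt(vp / w)
}

#' Effective sample size of one parameter
#'
#' Autocorrelation-based ESS over split chains with Geyer's initial positive,
#' monotone pair sequence; capped at the total number of retained draws.
#'
#' @param mat iterations x chains matrix.
#' @param max_lag autocovariance truncation (cost guard).
#' @return estimated effective sample size.
#' @export
ess_basic <- function(mat, max_lag = 500L) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 8L) return(NA_real_)
  half <- floor(n / 2)
  sp <- do.call(cbind, lapply(seq_len(ncol(mat)), function(cc) {
    cbind(mat[seq_len(half), cc], mat[half + seq_len(half), cc])
  }))
  m <- ncol(sp)
  total <- m * half
  lag_max <- min(half - 1L, max_lag)
  acov <- sapply(seq_len(m), function(cc) {
    drop(acf(sp[, cc], lag.max = lag_max, type = "covariance",
             plot = FALSE, demean = TRUE)$acf)
  })
  w <- mean(acov[1L, ]) * half / (half - 1)
  b <- half * var(colMeans(sp))
  vp <- (half - 1) / half * w + b / half
  if (!is.finite(vp) || vp <= 0) return(NA_real_)
  rho <- 1 - (w - rowMeans(acov)) / vp   # rho[1] corresponds to lag 0
  # Geyer: sum lag pairs while positive, enforce monotone decrease
  tau <- 0; prev <- Inf
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
    t <- t + 2L
  }
  ess <- total / max(2 * tau - 1, 1e-8)
  min(max(ess, 1), total)
}

#' Convergence diagnostics for a fit
#'
#' Split R-hat and effective sample size for every stored variable, the
#' divergence count, and a pass/fail verdict against the configured
#' thresholds.  Requires at least two chains.
#'
#' @param fit an `hs_fit`.
#' @return data.frame (`parameter`, `rhat`, `ess`) with attributes `pass`,
#'   `n_divergent`, `rhat_threshold`.
#' @export
diagnostics <- function(fit) {
  if (dim(fit$draws)[2] < 2L) stop("diagnostics require at least 2 chains")
  vars <- dimnames(fit$draws)[[3]]
  rhat <- vapply(vars, function(v) split_rhat(fit$draws[, , v]), numeric(1))
  ess <- vapply(vars, function(v) ess_basic(fit$draws[, , v]), numeric(1))
  out <- data.frame(parameter = vars, rhat = unname(rhat), ess = unname(ess))
  ndiv <- sum(fit$n_divergent)
  pass <- all(rhat <= fit$config$rhat_threshold, na.rm = TRUE) &&
    ndiv <= fit$config$max_divergent
  attr(out, "pass") <- pass
  attr(out, "n_divergent") <- ndiv
  attr(out, "rhat_threshold") <- fit$config$rhat_threshold
  out
}
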