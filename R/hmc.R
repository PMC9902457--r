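# A small Hamiltonian Monte Carlo engine: leapfrog integrator, dual-averaging
# step-size adaptation toward a target acceptance statistic, and a diagonal
# metric estimated from the middle of warm-up.  The model supplies `lpg`, a
# function returning list(lp = log-density, grad = its gradient) on the
# unconstrained scale; everything else is model-agnostic.

find_init_eps <- function(lpg, q, m_inv, cur) {
  p0 <- rnorm(length(q)) / sqrt(m_inv)
  h0 <- -cur$lp + 0.5 * sum(p0 * p0 * m_inv)
  log_ratio <- function(eps) {
    p <- p0 + 0.5 * eps * cur$grad
    q1 <- q + eps * (m_inv * p)
    nw <- tryCatch(lpg(q1), error = function(e) NULL)
    if (is.null(nw) || !is.finite(nw$lp) || any(!is.finite(nw$grad))) return(-Inf)
    p <- p + 0.5 * eps * nw$grad
    -(-nw$lp + 0.5 * sum(p * p * m_inv)) + h0
  }
  eps <- 0.1
  up <- log_ratio(eps) > log(0.5)
  for (k in 1:40) {
    eps2 <- eps * if (up) 2 else 0.5
    ok <- log_ratio(eps2) > log(0.5)
    if (ok != up) break
    eps <- eps2
    if (eps < 1e-8 || eps > 1e3) break
  }
  eps
}

#' Sample one HMC chain
#'
#' Generic driver used by [fit_hierarchical()]; exposed so that alternative
#' log-posteriors (e.g. the toy models used to validate the sampler) can be
#' run through exactly the same machinery.
#'
#' @param lpg function of the unconstrained parameter vector returning
#'   `list(lp =, grad =)`.
#' @param init initial unconstrained parameter vector.
#' @param n_warmup,n_draws warm-up (adaptation) and retained iteration counts.
#' @param seed optional seed for this chain.
#' @param control list: `adapt_delta` (target acceptance, default 0.8),
#'   `L` (range of leapfrog steps, default `c(8, 20)`), `max_delta_h`
#'   (divergence threshold on the energy error, default 1000).
#' @return list with `draws` (matrix draws x dim), `lp`, `n_divergent`,
#'   `accept_rate`, `eps`, `m_inv`.
#' @export
hmc_chain <- function(lpg, init, n_warmup, n_draws, seed = NULL,
                      control = list()) {
  ctl <- modifyList(list(adapt_delta = 0.8, L = c(8L, 20L),
                         max_delta_h = 1000), control)
  with_seed(seed, {
    d <- length(init)
    q <- init
    cur <- lpg(q)
    if (!is.finite(cur$lp)) stop("initial point has non-finite log density")
    m_inv <- rep(1, d)
    eps <- find_init_eps(lpg, q, m_inv, cur)
    mu_da <- log(10 * eps); h_bar <- 0; leps_bar <- log(eps)
    gamma <- 0.05; t0 <- 10; kappa <- 0.75; t_adapt <- 0
    draws <- matrix(NA_real_, n_draws, d)
    lp_out <- numeric(n_draws)
    n_div <- 0L; n_acc <- 0
    warm <- if (n_warmup > 0) matrix(NA_real_, n_warmup, d) else NULL
    metric_at <- if (n_warmup >= 100) floor(0.6 * n_warmup) else Inf
    lo <- as.integer(ctl$L[1]); hi <- as.integer(ctl$L[2])
    for (it in seq_len(n_warmup + n_draws)) {
      p <- rnorm(d) / sqrt(m_inv)
      h0 <- -cur$lp + 0.5 * sum(p * p * m_inv)
      L <- if (hi > lo) sample(lo:hi, 1L) else lo
      qn <- q
      p <- p + 0.5 * eps * cur$grad
      nw <- NULL; div <- FALSE; dh <- Inf
      for (l in seq_len(L)) {
        qn <- qn + eps * (m_inv * p)
        nw <- tryCatch(lpg(qn), error = function(e) NULL)
        if (is.null(nw) || !is.finite(nw$lp) || any(!is.finite(nw$grad))) {
          div <- TRUE; break
        }
        p <- p + (if (l < L) eps else 0.5 * eps) * nw$grad
      }
      if (!div) {
        dh <- (-nw$lp + 0.5 * sum(p * p * m_inv)) - h0
        if (!is.finite(dh) || dh > ctl$max_delta_h) div <- TRUE
      }
      a <- if (div) 0 else min(1, exp(-dh))
      if (!div && runif(1) < a) { q <- qn; cur <- nw }
      if (it <= n_warmup) {
        t_adapt <- t_adapt + 1
        h_bar <- (1 - 1 / (t_adapt + t0)) * h_bar +
          (ctl$adapt_delta - a) / (t_adapt + t0)
        leps <- mu_da - sqrt(t_adapt) / gamma * h_bar
        w <- t_adapt^(-kappa)
        leps_bar <- w * leps + (1 - w) * leps_bar
        eps <- exp(leps)
        warm[it, ] <- q
        if (it == metric_at) {
          win <- warm[floor(0.3 * n_warmup):it, , drop = FALSE]
          nn <- nrow(win)
          v <- apply(win, 2, var)
          m_inv <- (nn / (nn + 5)) * v + 1e-3 * (5 / (nn + 5))
          m_inv[!is.finite(m_inv) | m_inv <= 0] <- 1
          eps <- exp(leps_bar)
          mu_da <- log(10 * eps); h_bar <- 0; t_adapt <- 0; leps_bar <- log(eps)
        }
        if (it == n_warmup) eps <- exp(leps_bar)
      } else {
        if (div) n_div <- n_div + 1L
        n_acc <- n_acc + a
        draws[it - n_warmup, ] <- q
        lp_out[it - n_warmup] <- cur$lp
      }
    }
    list(draws = draws, lp = lp_out, n_divergent = n_div,
         accept_rate = n_acc / max(1, n_draws), eps = eps, m_inv = m_inv)
  })
}
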