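#include <Rcpp.h>
using namespace Rcpp;

// Log posteriors and analytic gradients for the hierarchical choice and
// belief-update models, on the unconstrained sampling scale used by the HMC
// driver (see R/hmc.R).  Group scales are sampled as log(sigma), individual
// inverse temperatures through a scaled-logistic transform onto [0, 5], and
// the k-weights use a non-centered parameterization k = mu + sigma * z.

static inline double invlogit(double x) {
  if (x >= 0.0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log(Phi((hi-mu)/sigma) - Phi((lo-mu)/sigma)) with gradients wrt mu, sigma.
// Needed so the truncated-Normal prior on beta is properly normalized for
// every (mu_beta, sigma_beta) -- without this term the hierarchy is tilted.
static double log_trunc_mass(double mu, double sigma, double lo, double hi,
                             double &dmu, double &dsig) {
  double a = (lo - mu) / sigma, b = (hi - mu) / sigma;
  // reflect into the lower tail where pnorm(log = TRUE) is accurate
  double aa = a, bb = b;
  if (a > 0.0) { aa = -b; bb = -a; }
  double lFb = R::pnorm(bb, 0.0, 1.0, 1, 1);
  double lFa = R::pnorm(aa, 0.0, 1.0, 1, 1);
  double d = lFa - lFb; // <= 0
  double lZ;
  if (d > -M_LN2) lZ = lFb + std::log(-std::expm1(d));
  else            lZ = lFb + std::log1p(-std::exp(d));
  double la = R::dnorm(a, 0.0, 1.0, 1), lb = R::dnorm(b, 0.0, 1.0, 1);
  double ra = std::exp(la - lZ), rb = std::exp(lb - lZ); // phi/Z, underflow-safe
  dmu = (ra - rb) / sigma;
  dsig = (a * ra - b * rb) / sigma;
  return lZ;
}

// ---------------------------------------------------------------------------
// Choice models (two-source softmax).  Layout of theta:
//   [ zAcc(n) | zPos(n) | braw(n) | muAcc lsAcc | muPos lsPos | muB lsB ]
// with the zAcc/zPos and matching hyper blocks present only when the model
// includes that predictor.  d_pos must already be gated by EQ for the
// tiebreak model; pid is 0-based participant index per trial.
// [[Rcpp::export]]
List cpp_choice_lpgrad(NumericVector theta, NumericVector d_acc,
                       NumericVector d_pos, IntegerVector chose,
                       IntegerVector pid, int n_sub,
                       bool has_acc, bool has_pos) {
  const int T = d_acc.size();
  const int n = n_sub;
  int off = 0;
  const int iZA = has_acc ? off : -1; if (has_acc) off += n;
  const int iZP = has_pos ? off : -1; if (has_pos) off += n;
  const int iBR = off; off += n;
  const int iMA = has_acc ? off : -1; if (has_acc) off += 2;
  const int iMP = has_pos ? off : -1; if (has_pos) off += 2;
  const int iMB = off; off += 2;
  if (theta.size() != off) stop("parameter vector has wrong length");

  NumericVector g(off);
  double lp = 0.0;

  double muA = 0, sA = 1, muP = 0, sP = 1;
  if (has_acc) { muA = theta[iMA]; sA = std::exp(theta[iMA + 1]); }
  if (has_pos) { muP = theta[iMP]; sP = std::exp(theta[iMP + 1]); }
  const double muB = theta[iMB], lsB = theta[iMB + 1];
  const double sB = std::exp(lsB);

  double dZmu = 0, dZsig = 0;
  const double lZ = log_trunc_mass(muB, sB, 0.0, 5.0, dZmu, dZsig);
  const double LOG2PI = std::log(2.0 * M_PI);

  std::vector<double> kA(n, 0.0), kP(n, 0.0), beta(n);
  for (int i = 0; i < n; ++i) {
    if (has_acc) {
      double z = theta[iZA + i]; kA[i] = muA + sA * z;
      lp += -0.5 * z * z; g[iZA + i] -= z;
    }
    if (has_pos) {
      double z = theta[iZP + i]; kP[i] = muP + sP * z;
      lp += -0.5 * z * z; g[iZP + i] -= z;
    }
    double br = theta[iBR + i];
    double s = invlogit(br);
    double b = 5.0 * s;
    beta[i] = b;
    // truncated-Normal(muB, sB) on [0,5] prior + log-Jacobian of b(braw)
    double r = (b - muB) / sB;
    lp += -0.5 * r * r - lsB - 0.5 * LOG2PI - lZ;
    lp += std::log(5.0) + std::log(s) + std::log1p(-s);
    double J = 5.0 * s * (1.0 - s);
    g[iBR + i] += (-r / sB) * J + (1.0 - 2.0 * s);
    g[iMB]     += r / sB - dZmu;
    g[iMB + 1] += (r * r - 1.0) - sB * dZsig;
  }

  // hyperpriors: mu_k ~ N(0,1), mu_beta ~ N(0,2), sigmas ~ Gamma(1, 0.5)
  if (has_acc) {
    lp += -0.5 * muA * muA;                       g[iMA]     -= muA;
    lp += std::log(0.5) + theta[iMA + 1] - 0.5 * sA; g[iMA + 1] += 1.0 - 0.5 * sA;
  }
  if (has_pos) {
    lp += -0.5 * muP * muP;                       g[iMP]     -= muP;
    lp += std::log(0.5) + theta[iMP + 1] - 0.5 * sP; g[iMP + 1] += 1.0 - 0.5 * sP;
  }
  lp += -muB * muB / 8.0;                 g[iMB]     -= muB / 4.0;
  lp += std::log(0.5) + lsB - 0.5 * sB;   g[iMB + 1] += 1.0 - 0.5 * sB;

  // Bernoulli likelihood through the softmax on value differences
  for (int t = 0; t < T; ++t) {
    int i = pid[t];
    double v = 0.0;
    if (has_acc) v += kA[i] * d_acc[t];
    if (has_pos) v += kP[i] * d_pos[t];
    double sc = beta[i] * v;
    double y = (double) chose[t];
    lp += y * sc - softplus(sc);
    double resid = y - invlogit(sc);
    if (has_acc) {
      double dk = resid * beta[i] * d_acc[t];
      g[iMA] += dk; g[iMA + 1] += dk * sA * theta[iZA + i]; g[iZA + i] += dk * sA;
    }
    if (has_pos) {
      double dk = resid * beta[i] * d_pos[t];
      g[iMP] += dk; g[iMP + 1] += dk * sP * theta[iZP + i]; g[iZP + i] += dk * sP;
    }
    double s = invlogit(theta[iBR + i]);
    g[iBR + i] += resid * v * 5.0 * s * (1.0 - s);
  }

  return List::create(_["lp"] = lp, _["grad"] = g);
}

// ---------------------------------------------------------------------------
// Belief-update models (Gaussian, multiplicative win-direction asymmetry).
// Layout of theta:
//   [ kC(n) | kA(n) | kP(n)? | kS(n) | lsU(n) |
//     muC lsC | muA lsA | muP lsP? | etaS lsS ]
// where mu_kSym = exp(etaS) so that log(mu_kSym) ~ Normal(0,1).  The k-blocks
// are *centered* (sampled on their natural scale): every participant
// contributes 40 informative trials, where a non-centered parameterization
// couples the hypers to all individual offsets and mixes poorly.
// [[Rcpp::export]]
List cpp_belief_lpgrad(NumericVector theta, NumericVector acc_c,
                       NumericVector pos_c, IntegerVector dir,
                       NumericVector U, IntegerVector pid, int n_sub,
                       bool has_pos) {
  const int T = U.size();
  const int n = n_sub;
  int off = 0;
  const int iZC = off; off += n;
  const int iZA = off; off += n;
  const int iZP = has_pos ? off : -1; if (has_pos) off += n;
  const int iZS = off; off += n;
  const int iLU = off; off += n;
  const int iMC = off; off += 2;
  const int iMA = off; off += 2;
  const int iMP = has_pos ? off : -1; if (has_pos) off += 2;
  const int iES = off; off += 2;
  if (theta.size() != off) stop("parameter vector has wrong length");

  NumericVector g(off);
  double lp = 0.0;

  const double muC = theta[iMC], sC = std::exp(theta[iMC + 1]);
  const double muA = theta[iMA], sA = std::exp(theta[iMA + 1]);
  double muP = 0, sP = 1;
  if (has_pos) { muP = theta[iMP]; sP = std::exp(theta[iMP + 1]); }
  const double etaS = theta[iES], sS = std::exp(theta[iES + 1]);
  const double mS = std::exp(etaS);

  std::vector<double> kC(n), kA(n), kP(n, 0.0), kS(n), sU(n);
  const double LOGSQRT2PI = 0.5 * std::log(2.0 * M_PI);
  for (int i = 0; i < n; ++i) {
    double r;
    kC[i] = theta[iZC + i]; r = (kC[i] - muC) / sC;
    lp += -0.5 * r * r - theta[iMC + 1] - LOGSQRT2PI;
    g[iZC + i] -= r / sC; g[iMC] += r / sC; g[iMC + 1] += r * r - 1.0;
    kA[i] = theta[iZA + i]; r = (kA[i] - muA) / sA;
    lp += -0.5 * r * r - theta[iMA + 1] - LOGSQRT2PI;
    g[iZA + i] -= r / sA; g[iMA] += r / sA; g[iMA + 1] += r * r - 1.0;
    if (has_pos) {
      kP[i] = theta[iZP + i]; r = (kP[i] - muP) / sP;
      lp += -0.5 * r * r - theta[iMP + 1] - LOGSQRT2PI;
      g[iZP + i] -= r / sP; g[iMP] += r / sP; g[iMP + 1] += r * r - 1.0;
    }
    kS[i] = theta[iZS + i]; r = (kS[i] - mS) / sS;
    lp += -0.5 * r * r - theta[iES + 1] - LOGSQRT2PI;
    g[iZS + i] -= r / sS; g[iES] += (r / sS) * mS; g[iES + 1] += r * r - 1.0;
    double lu = theta[iLU + i]; sU[i] = std::exp(lu);
    lp += std::log(0.5) + lu - 0.5 * sU[i];   // sigma_U ~ Gamma(1, 0.5) + Jacobian
    g[iLU + i] += 1.0 - 0.5 * sU[i];
  }

  lp += -0.5 * muC * muC;  g[iMC] -= muC;
  lp += -0.5 * muA * muA;  g[iMA] -= muA;
  if (has_pos) { lp += -0.5 * muP * muP; g[iMP] -= muP; }
  lp += -0.5 * etaS * etaS; g[iES] -= etaS;
  lp += std::log(0.5) + theta[iMC + 1] - 0.5 * sC; g[iMC + 1] += 1.0 - 0.5 * sC;
  lp += std::log(0.5) + theta[iMA + 1] - 0.5 * sA; g[iMA + 1] += 1.0 - 0.5 * sA;
  if (has_pos) {
    lp += std::log(0.5) + theta[iMP + 1] - 0.5 * sP; g[iMP + 1] += 1.0 - 0.5 * sP;
  }
  lp += std::log(0.5) + theta[iES + 1] - 0.5 * sS; g[iES + 1] += 1.0 - 0.5 * sS;

  const double LOG2PI = std::log(2.0 * M_PI);
  for (int t = 0; t < T; ++t) {
    int i = pid[t];
    double lin = kC[i] + kA[i] * acc_c[t] + (has_pos ? kP[i] * pos_c[t] : 0.0);
    double mult = 1.0 + (kS[i] - 1.0) * dir[t];
    double muU = lin * mult;
    double res = U[t] - muU;
    double s2 = sU[i] * sU[i];
    lp += -0.5 * res * res / s2 - theta[iLU + i] - 0.5 * LOG2PI;
    double e = res / s2;
    g[iZC + i] += e * mult;
    g[iZA + i] += e * mult * acc_c[t];
    if (has_pos) g[iZP + i] += e * mult * pos_c[t];
    g[iZS + i] += e * lin * dir[t];
    g[iLU + i] += res * res / s2 - 1.0;
  }

  return List::create(_["lp"] = lp, _["grad"] = g);
}

// ---------------------------------------------------------------------------
// Marginal likelihood of one participant's data for a *new* participant,
// integrating the individual parameters over the group-level distribution by
// plain Monte Carlo with M inner draws per posterior draw.  Used both for
// the held-out predictive density and for the TIS-LOO importance weights.

static double rtnorm_0_5(double mu, double sig) {
  double Fa = R::pnorm(0.0, mu, sig, 1, 0);
  double Fb = R::pnorm(5.0, mu, sig, 1, 0);
  double w = Fb - Fa;
  if (w < 1e-12) return mu < 0.0 ? 0.0 : (mu > 5.0 ? 5.0 : mu);
  double u = Fa + unif_rand() * w;
  if (u <= 0.0) u = 1e-16;
  if (u >= 1.0) u = 1.0 - 1e-16;
  double x = R::qnorm(u, mu, sig, 1, 0);
  if (x < 0.0) x = 0.0;
  if (x > 5.0) x = 5.0;
  return x;
}

// hyper columns: mu_acc, sigma_acc, mu_pos, sigma_pos, mu_beta, sigma_beta
// [[Rcpp::export]]
NumericVector cpp_choice_marg_ll(NumericMatrix hyper, NumericVector d_acc,
                                 NumericVector d_pos, IntegerVector chose,
                                 int M, bool has_acc, bool has_pos) {
  const int S = hyper.nrow(), T = d_acc.size();
  NumericVector out(S);
  std::vector<double> lls(M);
  for (int s = 0; s < S; ++s) {
    for (int m = 0; m < M; ++m) {
      double kA = has_acc ? R::rnorm(hyper(s, 0), hyper(s, 1)) : 0.0;
      double kP = has_pos ? R::rnorm(hyper(s, 2), hyper(s, 3)) : 0.0;
      double beta = rtnorm_0_5(hyper(s, 4), hyper(s, 5));
      double ll = 0.0;
      for (int t = 0; t < T; ++t) {
        double v = 0.0;
        if (has_acc) v += kA * d_acc[t];
        if (has_pos) v += kP * d_pos[t];
        double sc = beta * v;
        ll += chose[t] * sc - softplus(sc);
      }
      lls[m] = ll;
    }
    double mx = *std::max_element(lls.begin(), lls.end());
    double acc = 0.0;
    for (int m = 0; m < M; ++m) acc += std::exp(lls[m] - mx);
    out[s] = mx + std::log(acc / M);
  }
  return out;
}

// hyper columns: mu_cons, sigma_cons, mu_acc, sigma_acc, mu_pos, sigma_pos,
//                mu_sym, sigma_sym   (mu_sym already on the natural scale)
// [[Rcpp::export]]
NumericVector cpp_belief_marg_ll(NumericMatrix hyper, NumericVector acc_c,
                                 NumericVector pos_c, IntegerVector dir,
                                 NumericVector U, int M, bool has_pos) {
  const int S = hyper.nrow(), T = U.size();
  NumericVector out(S);
  std::vector<double> lls(M);
  for (int s = 0; s < S; ++s) {
    for (int m = 0; m < M; ++m) {
      double kC = R::rnorm(hyper(s, 0), hyper(s, 1));
      double kA = R::rnorm(hyper(s, 2), hyper(s, 3));
      double kP = has_pos ? R::rnorm(hyper(s, 4), hyper(s, 5)) : 0.0;
      double kS = R::rnorm(hyper(s, 6), hyper(s, 7));
      double sU = R::rgamma(1.0, 2.0);  // shape 1, scale 2 == rate 0.5
      double ll = 0.0;
      for (int t = 0; t < T; ++t) {
        double lin = kC + kA * acc_c[t] + (has_pos ? kP * pos_c[t] : 0.0);
        double muU = lin * (1.0 + (kS - 1.0) * dir[t]);
        ll += R::dnorm(U[t], muU, sU, 1);
      }
      lls[m] = ll;
    }
    double mx = *std::max_element(lls.begin(), lls.end());
    double acc = 0.0;
    for (int m = 0; m < M; ++m) acc += std::exp(lls[m] - mx);
    out[s] = mx + std::log(acc / M);
  }
  return out;
}
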