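---
title: "Models, priors, and design decisions in hedoseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, priors, and design decisions in hedoseek}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hedoseek studies a simple question with two lottery-prediction paradigms:
when people can choose where their information comes from, how much weight
do they put on a source's *accuracy* versus the *positivity* of what it
tends to say, and does positivity change how strongly its messages are
believed?  This vignette documents the models, the priors, the sampler, the
synthetic-data generator, and the numerical decisions behind the package —
including the places where the design was genuinely open and we had to
choose.

## Task design

A "psychic" makes five example predictions about coin-flip lotteries whose
outcomes are then revealed.  Its profile is the pair (`nAcc`, `nPos`):
correct predictions and "win" predictions among the five.  Not every
profile is realizable for a given number of true wins `w`: a wrong
prediction about a losing lottery is necessarily a "win" prediction, which
forces `nAcc + nPos + w` to be odd and bounds the number of correctly
predicted wins, `x = (nAcc + nPos + w - 5)/2`, by
`max(0, nAcc + w - 5) <= x <= min(nAcc, w)`.  With the minimum-accuracy
rule `nAcc >= 3` (which guarantees that betting against a psychic is never
the better strategy) there are 28 feasible profiles across `w = 0..5` and
exactly **56** combinations of `w` with an unordered pair of two distinct
profiles.  `enumerate_pair_combinations()` asserts that count at run time,
and the test suite re-derives the profile sets by brute force over all 32
prediction patterns.

Two open details are resolved as follows:

- *What counts as a "combination"?*  The convention whose total matches the
  printed 56 — `(w, unordered pair of distinct (nAcc, nPos) profiles)` —
  with identical-profile pairs excluded.  This is inferred from the
  arithmetic (3 + 10 + 15 + 15 + 10 + 3), not stated anywhere.
- *Which 16 combinations make up a session?*  The original 16-trial subset
  was manually curated and is not public.  `default_exp1_combos()` is a
  documented stratified stand-in covering every `w`, equal- and
  unequal-accuracy pairs, and both orderings of accuracy versus positivity
  advantage.  Every entry point accepts a custom combination table.
- *Experiment 2 combinations.*  All feasible `(w, profile)` pairs with
  `w` in {2, 3} and `nAcc` in {3, 4}; brute-force enumeration gives 10
  combinations, hence 40 trials at four repetitions each (two win- and two
  loss-direction predictions, two repetitions per experiment half).

## Choice models (Experiment 1)

The value of source X for participant i is a linear combination of its
centered covariates, `V(X) = k_Acc nAcc_X + k_Pos nPos_X`, entered into a
two-option softmax with inverse temperature `beta in [0, 5]`.  The four
variants drop one weight, keep both, or gate the positivity weight by the
equal-accuracy indicator `EQ` (tiebreak model).  Two notes:

- The published model description assigns both 0 and 1 to "equally accurate" when defining
  `EQ` (an evident typo); we implement `EQ = 1` iff the two psychics are
  equally accurate, which is the only reading consistent with "used only
  as a tiebreaker".
- Covariates are centered at the pooled mean over every *presented*
  psychic.  Whether centering is per participant or pooled is not
  specified; pooled is used (and since every participant sees the same
  combination set, the two coincide for complete data).  In the softmax
  only value *differences* matter, so choice likelihoods are unaffected by
  centering either way; it is kept for interface symmetry with the belief
  models, where absolute covariates do matter.

## Belief models (Experiment 2)

Ratings on the 0–100 scale are converted to signed updates
`U = rating - 50` after a win prediction and `U = 50 - rating` after a loss
prediction, so positive updates always point toward the prediction.  The
full model is

`U ~ Normal((k_Cons + k_Acc nAcc_c + k_Pos nPos_c) * (1 + (k_Sym - 1) Dir), sigma_U)`

with the no-positivity variant dropping `k_Pos`.  `k_Sym` multiplies the
mean update on win-direction trials only; it deliberately confounds
optimism bias (shifted starting points) with asymmetric updating, because
the two predict identical update patterns and separating them would make
the model unrecoverable.  `k_Sym`'s individual-level prior is an
untruncated Normal, so negative draws are possible and the sampler must
tolerate them; the synthetic defaults use `mu_kSym = 1.5` with a small
group scale, keeping such draws rare.  Boundary ratings (0/100) are treated
as ordinary Gaussian observations — how the original analysis handled them
is unstated — and the generator clips simulated ratings to the response
scale while logging clip counts (default regimes clip well under 1% and a
test asserts zero clipping at the default parameters).

## Priors and inference

Hyperpriors are exactly the printed ones: `mu_kAcc, mu_kPos, mu_kCons ~
Normal(0, 1)`, `mu_beta ~ Normal(0, 2)`, `log(mu_kSym) ~ Normal(0, 1)`,
and every group scale and `sigma_U ~ Gamma(1, 0.5)` (shape–rate, mean 2).
Individual weights are Normal around their group means; `beta` is Normal
truncated to [0, 5].

No Stan-class engine is available in the build environment, so inference is
a purpose-built Hamiltonian Monte Carlo sampler: leapfrog integration,
dual-averaging step-size adaptation toward a target acceptance rate
(default 0.9), a diagonal metric estimated from the middle warm-up window,
jittered trajectory lengths, and divergence counting (energy-error
threshold 1000, with non-finite states rejected).  The engine is generic —
any `lp`/gradient pair can be run through `hmc_chain()` — and the model
gradients are analytic, compiled, and verified against finite differences
in the test suite.

Parameterization choices worth recording:

- `beta` is sampled through a scaled-logistic transform onto [0, 5] with
  the *normalized* truncated-Normal prior (the `log Phi`-difference term
  and its gradients are included).  Merely declaring bounds, as casual Stan
  code does, tilts the hierarchy; with the normalization, prior-only runs
  reproduce `mu_beta ~ Normal(0, 2)` exactly, which a test checks against
  direct prior sampling.
- The choice-model weights are *non-centered* (`k = mu + sigma z`): with 64
  Bernoulli trials per participant the individual likelihood is diffuse
  enough that the non-centered form mixes better.
- The belief-model weights are *centered*: every participant contributes 40
  Gaussian trials that pin the individual parameters tightly, and the
  non-centered form then couples the hypers to every offset and can stick
  (we observed split R-hats above 5 on `mu_kSym` before switching).
  Centered-vs-non-centered equivalence is verified on an analytically
  tractable toy hierarchy through the same HMC driver.
- The remaining hard geometry is real, not an artifact: in the softmax,
  `beta` multiplies the weights, so only the products are likelihood-
  identified and the prior must resolve the scale (a known property of this
  model family); in the belief model, the ±0.5 centered accuracy design
  makes `k_Cons` and `k_Acc` strongly correlated per participant.  Long
  trajectories (32–160 leapfrog steps) are the remedy, and the test-scale
  configurations encode that.

Convergence is judged by split R-hat (threshold 1.01 by default — the
original protocol prescribes no threshold, so we adopt the modern convention), ESS, and a
zero-divergence tolerance; failures are warned about and recorded in the
fit object, never silently accepted.  The default configuration matches
the original protocol (4 chains, 1500 warm-up, 5000 retained draws, read as
per chain; the text is ambiguous between per-chain and total, and per-chain
is the generous reading).  Point estimates default to posterior means, with
medians available — "final parameter estimates" is otherwise unspecified.

## Model comparison

`pointwise_loglik()` evaluates every observation at every retained draw.
From it: WAIC (`-2(lppd - p_waic)`, deviance scale, per-observation
standard errors), and participant-wise leave-one-out elpd where the
held-out participant's parameters are integrated over the group-level
distribution by Monte Carlo (`inner_draws` fresh draws per posterior draw),
i.e. prediction for a *new* participant.  Two estimators are provided:

- `exact_refit` — refit without the participant, then average the marginal
  likelihood over the refitted posterior (the oracle);
- `tis` — truncated importance sampling over the full-data posterior, raw
  weights `1/p(y_i | hyper_s)` capped at `mean(weight) * sqrt(S)` (the
  standard truncation rule; the source cites but does not restate it).

Because the marginal enters the TIS weights as a reciprocal, Monte-Carlo
noise in the nested estimate produces a downward Jensen bias of order
`cv^2 / inner_draws`; the agreement test therefore uses a large inner draw
count, and reported Monte-Carlo standard errors are scaled by the
effective sample size of the integrand sequence rather than the raw draw
count.  Stacking weights maximize the log pointwise density of the model
mixture by multiplicative (EM) updates from a uniform start — the problem
is concave, identical models receive equal weights by convention, and a
grid-search oracle confirms optimality in the tests.  Best-predictor
proportions split exact ties equally.  The standard error attached to a
summed elpd is the participant-level `sqrt(n * var)` convention; the
per-observation alternative is not used anywhere.

## ROPE and recovery analyses

The region of practical equivalence for a belief hyperparameter is the
coefficient magnitude at which the maximal change in its predictor moves
the updates by 0.1 standard deviations: bounds `±0.1 sd(U) / delta_max`
with `delta_max = 5` for positivity (five win- vs five loss-predictions)
and 1 for accuracy (four vs three correct), on the raw-difference scale
(slopes per raw and per centered unit coincide).  `sd(U)` is the pooled
standard deviation of the quantified updates; per-participant pooling is
deliberately not the default since the decision is about group-level
hyperparameters.  The 95% HDI is the narrowest contiguous window over the
sorted draws (unimodality assumed); a parameter is practically zero iff
its HDI lies inside the ROPE, meaningfully nonzero iff they are disjoint,
undecided otherwise.

Model recovery simulates cohorts from each candidate model at
well-separated regimes (strong weights, high `beta`), fits all candidates,
and classifies by summed leave-one-participant-out elpd (the same metric
used for the real comparison).  Parameter recovery correlates true and
posterior-mean individual parameters and checks hyperparameter credible-
interval coverage.

## The synthetic cohorts: what they are and are not

The behavioural data are available only on request, so every empirical
claim in this package is about *synthetic* cohorts generated by the models
themselves.  Defaults are chosen once to mirror the qualitative findings —
accuracy weighted above positivity, both positive (`mu_kAcc = 2`,
`mu_kPos = 0.7`, `mu_beta = 2`), and good-news amplification
(`mu_kSym = 1.5`); group scales are set to values a behavioural cohort
would plausibly show (individual weights spanning roughly half their mean).
They are illustrative, not estimates.  Two Experiment-1 fields — block-level
win estimates and confidence ratings — are generated by a simple anchoring
model (estimates pulled between shown wins and the 8-win base rate;
confidence increasing in shown wins) purely so the end-to-end pipeline has
those columns; they are labelled plumbing and feed no model.

Consequently, a green test establishes that the *machinery* behaves as
specified — combinatorics exact, likelihoods equal to oracles, generative
model identifiable, parameters recoverable, the ROPE pattern reproduced
when the generating truth matches it — not that any human cohort shows
these effects, and the headline statistics of the original study (t-tests,
mixed-effects regressions, the Table-1 elpd values on 158 participants)
are out of reach by construction.  One visible consequence of taking the
printed priors seriously: `mu_kCons` around 5 rating points is shrunk
noticeably by its `Normal(0, 1)` hyperprior in small cohorts, so its
credible interval can exclude the generating value while every other
hyperparameter is covered.  That is the model as specified, not a sampler
defect.

## Numerical details and degenerate inputs

- Softmax probabilities and Bernoulli log-likelihoods go through
  `log1p(exp(·))`-style guards; `log(Phi(b) - Phi(a))` is computed in log
  space with tail reflection, so extreme `(mu_beta, sigma_beta)` values do
  not underflow.
- Stacking EM iterates to a 1e-10 weight tolerance; WAIC needs at least
  two draws (variance is undefined otherwise) and errors on one; the HDI
  requires 100 draws; `rope_interval` rejects non-positive standard
  deviations; empty datasets error in centering, pointwise likelihoods and
  predictive checks, but an empty dataset with an explicit participant
  list is the supported prior-only sampling mode.
- Ties: softmax choices are Bernoulli draws, never deterministic;
  best-model ties split equally; the equal-accuracy indicator uses exact
  integer equality.
- All randomness flows from user-supplied seeds through a single
  deterministic fan-out (`with_seed` restores the caller's RNG state), so
  schedules, cohorts, fits and pipeline artifacts are reproducible
  byte-for-byte under a fixed seed.

## Known limitations

- Static HMC with a diagonal metric, not NUTS with a dense one: the
  documented ridges cost effective sample size at test scale (split R-hat
  around 1.05–1.1 on the slowest belief-model coordinates with two short
  chains); full-scale configurations mix cleanly.
- TIS-LOO inherits the nested-marginal Jensen bias discussed above; with
  few participants and small inner draw counts it is visibly pessimistic.
- The HDI assumes unimodality; multimodal posteriors are out of scope.
- Learning or trial-order effects are deliberately absent everywhere —
  trials are exchangeable given parameters, as in the models themselves.
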