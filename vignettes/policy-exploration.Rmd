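---
title: "Modelling policy exploration and value transfer in multi-dimensional reward learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling policy exploration and value transfer in multi-dimensional reward learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polexplore)
```

## The task and the scientific question

`polexplore` models behaviour in an uninstructed multi-dimensional reward
learning task. On each of 256 trials (8 stages of 32) the subject sees one
of 8 stimuli that combine three binary features — shape (square/circle),
colour (blue/yellow) and pattern (vertical/horizontal) — and either *goes*
(accepts the gamble) or *passes* (0 points). Two "all-match" stimuli
(blue-square-vertical, yellow-circle-horizontal) always pay +10 on a go;
the two stimuli that differ from an all-match stimulus only in pattern
always pay -10; the remaining four pay +/-10 with equal probability. A
variant experiment (10 stages, 320 trials) penalises the shape or colour
non-match pair instead. Nothing about the features is instructed, so
subjects must discover *which feature combinations matter* while learning
*what each combination is worth*.

The analysis asks three questions. Which feature subset (policy) is a
subject using on each trial? When do they abandon one policy for another —
and is that moment marked by high cognitive ambiguity? And when they adopt
a richer policy, do they re-learn its values from scratch or inherit what
they already learned?

## Value learning within a policy

A *policy* $\pi_i$ is a non-empty subset of the three features; there are
seven, ordered 1–3 (single features), 4–6 (pairs), 7 (all three). A policy
projects the 8 stimuli onto $2^d$ states ($d$ = number of features used).
Within a policy, state–action values follow the delta rule

$$Q^{new}(s, a) = Q^{old}(s, a) + \alpha\,(R_t - Q^{old}(s, a)),$$

updating only the chosen action's entry, with learning rate
$\alpha \in [0, 1]$ and values initialised at zero. Choices follow a
softmax over the two actions,

$$p(a \mid s) = \frac{e^{\beta Q(s,a)}}{\sum_{a'} e^{\beta Q(s,a')}},$$

with inverse temperature $\beta \ge 0$. A session's likelihood is the
product of the per-trial probabilities of the observed choices; missed
trials (no response) are excluded everywhere. Both actions carry learnable
values: a chosen pass (always 0 points) relaxes $q_{pass}$ toward 0, which
keeps the update rule uniform across actions.

## Inferring the policy in use

Seven per-policy value learners run in parallel over a session; two models
then turn their outputs into per-trial policy probabilities.

The **softmax-based search** treats trials as independent: the probability
of policy $i$ at trial $t$ is proportional to
$\exp(Q_i(s_t, a_t)/\tau)$, the value policy $i$ assigned (pre-update) to
the action the subject actually took, with fixed temperature $\tau = 1$
(not fitted, so the model keeps the 7 fitted $(\alpha_i, \beta_i)$ pairs —
14 parameters).

The **HMM-based search** treats the policy as a hidden state with a sticky
transition matrix (self-transition 0.9, fixed; the remainder spread evenly)
and forward-filters from a uniform prior, with each policy's softmax
probability of the observed action as emission. Only forward filtering is
used — inference at trial $t$ relies on probabilities from trial $t-1$, not
on future data. Alongside the filtered posterior the implementation keeps
the one-step-ahead *predictive* distribution, because the product of
predictive-mixture choice probabilities equals the exact joint likelihood
marginalised over all policy paths (the test suite verifies this against
brute-force enumeration of all $7^T$ paths).

Policy-probability trajectories are smoothed by an ordinary least-squares
polynomial of degree 5 in (rescaled) trial index before taking the
per-trial argmax that defines the *current policy*; smoothing suppresses
single-trial flicker in the argmax. Exact ties break toward lower
dimensionality, then lower id. A *transition* is any trial whose current
policy differs from the previous trial's. Cognitive ambiguity is the
Shannon entropy $H(\pi) = -\sum_i P(\pi_i)\log P(\pi_i)$ of the
(unsmoothed) posterior, in nats, between 0 and $\log 7$.

Sessions are classified by the modal current-policy dimensionality in the
first versus last quarter of trials: `2d_to_3d`, `3d_to_2d`, `only_2d`,
`only_3d`; sessions dominated by a one-feature policy are `one_dim`, and
remaining combinations `other`.

## Value transfer at policy transitions

The value-transfer model replays a session with a *single* active policy
per trial (the schedule being the softmax-search current-policy series,
held fixed during fitting) and one shared $(\alpha, \beta)$ — 2 free
parameters. At each transition the incoming policy's table is initialised
by one of two rules:

* **zero**: all values reset to 0 (re-learn from scratch);
* **inherited**: each new state takes the unweighted mean of the previous
  policy's values over the old states consistent with it on the shared
  features. When the new policy refines the old one, exactly one old state
  is consistent and the mean degenerates to a direct copy; on a
  dimensionality decrease it averages the projection fibre; if the two
  policies share no features it is the grand mean. Both action columns
  transfer, and no additional weighting is applied.

A third benchmark, *policy 7 + noise*, runs plain delta-rule learning on
the full policy with a lapse rate $\varepsilon$ mixing the softmax with
chance (3 parameters).

## Fitting and model comparison

All fits maximise the session log-likelihood with a deterministic coarse
grid (5 values of $\alpha$, 5 log-spaced values of $\beta$, crossed with 3
lapse values where applicable) followed by bounded L-BFGS-B refinement of
the best starts, so refits reproduce exactly. Bounds are
$\alpha \in [0, 1]$, $\beta \in (0, 50]$ (fitted inverse temperatures in
this paradigm are strongly right-skewed, so the bound is generous),
$\varepsilon \in [0, 1]$. Estimation is staged as in the analysis the
package implements: (1) the seven per-policy $(\alpha_i, \beta_i)$, each by
its own likelihood; (2) posterior, smoothing and schedule; (3) the transfer
and baseline parameters with the schedule frozen. Models are scored by
$AIC = 2k - 2\log L$ and $BIC = k\log n - 2\log L$ with $n$ the number of
responded trials, and compared across sessions by paired two-sided
t-tests. The search models' likelihood is the posterior-weighted mixture of
per-policy choice probabilities (for the HMM, the predictive mixture).

## The synthetic cohort

No subject data ships with the package; a synthetic-agent module generates
cohorts with the statistical structure the analysis assumes, and every
generator parameter is recorded in a manifest sufficient to reproduce any
session bit-exactly.

* `random_agent()` — the fair-coin null behind the chance-level cutoff
  (the 95th percentile of 100,000 simulated session scores; the null score
  decomposes over reward categories, with analytic SD
  $\sqrt{64\cdot 25 + 64\cdot 25 + 128\cdot 50} = 98$ points).
* `fixed_policy_agent()` — delta-rule/softmax learning on one policy's
  state-space, never switching. Cohorts of these agents reproduce the
  design property that full-feature learners outscore lower-dimensional
  ones.
* `scheduled_transfer_agent()` — the value-transfer model run generatively
  along a prescribed policy schedule: the *known generator* for parameter-
  and model-recovery studies. Schedules come from
  `make_exploration_schedule()`: a few change points concentrated in early
  trials, tending from lower- to higher-dimensional policies.
* `exploring_transfer_agent()` — an autonomous explorer. It acts by
  softmax on its active policy plus a go-biased lapse (default 0.15; the
  "curiosity presses" without which passing starves the agent of
  information), learns background tables for all seven policies, and
  tracks ambiguity as the entropy of a posterior proportional to
  $\exp(\max_a Q_i(s_t,a) / \tau_a)$ with $\tau_a = 2$ (a fifth of the
  reward magnitude: fully learned values concentrate the posterior, single
  lucky rewards do not), averaged over the last 16 trials (ambiguity as a
  slowly varying cognitive state). When windowed ambiguity exceeds
  $0.8\log 7$ nats it switches with probability 0.1 per trial to a policy
  drawn from the window-averaged posterior, initialising the new table by
  the inherited (or zero) rule. These defaults were chosen once, on
  phenomenological grounds — a handful of transitions per 256 trials,
  concentrated early, with agents eventually settling and spanning a range
  of final scores — and define the study conditions for all cohort-level
  tests.

The generative switching law is the package's own construction: the
empirical analyses establish that transitions co-occur with high entropy,
but no generative mechanism is implied by them.

### What the recovery studies do and do not show

Parameter recovery simulates 50 sessions from the transfer model at known
$(\alpha, \beta) = (0.25, 5)$ and fits the same model *conditional on the
generating schedule*. This isolates the likelihood machinery for
$(\alpha, \beta)$ — the quantity the recovery criterion concerns — from
schedule identification, which is a separate and harder problem (below).
Model recovery refits every model exactly as on real data (schedule
re-derived by the search) and checks that inherited-value transfer wins the
cohort-mean AIC/BIC against zero initialisation, the 14-parameter search
model, and the lapse baseline.

## Numerical choices

* Choice probabilities are floored at $10^{-12}$ before logs; softmax uses
  max-subtraction; the improbable action's probability is computed directly
  from the exponentials rather than as $1-p$, so it stays positive.
* Entropy uses $0\log 0 = 0$.
* State indices encode feature levels (square/blue/vertical = 0) in the
  fixed order shape, colour, pattern, least-significant first, 1-based.
* Trial indices are 1-based in files; missed trials are representable in
  the session format (reward 0, excluded from all likelihoods and from the
  BIC $n$) but never produced by the synthetic agents.
* Degenerate inputs error loudly: fewer trials than polynomial degree + 1,
  sessions without transitions in cohort tests (excluded and counted),
  zero-variance regressors.

## Known limitations

* **Two-feature free-riding.** The softmax search scores a policy by the
  value it assigns to the chosen action. Once behaviour is near-optimal, a
  two-feature policy whose lumped state contains one rewarded and one
  penalised stimulus keeps a high go-value (the penalised stimulus is no
  longer chosen, so nothing pulls the value down) and ties with the full
  policy; the lower-dimensionality tie-break then labels genuinely
  three-feature behaviour as two-feature. Strategy classification of
  synthetic full-policy agents is therefore systematically conservative,
  and cohort-level class-recovery rates should be read with that in mind.
* **HMM advantage on fixed-policy data.** A synthetic agent that never
  switches policy is exactly the sticky HMM's favoured regime, and the
  HMM's likelihood is the proper marginal over policy paths, while the
  value-scored softmax posterior is uninformative on every pass trial
  (all $q_{pass}$ stay 0). On such cohorts the HMM search model attains
  better AIC/BIC than the softmax search — the opposite of the ordering
  reported for human subjects, whose policy use evidently tracked values
  rather than temporal persistence. The package reports this comparison as
  measured.
* **Compressed transition entropy.** Because detected transitions sit where
  smoothed probability curves cross — locally flat, high-entropy posterior
  regions — entropy-at-transition varies little over a session. The paired
  elevation of entropy at transitions is small, and the regression of
  entropy-at-transition on trial index is essentially flat on synthetic
  cohorts, so the "earlier transitions, higher entropy" gradient should be
  treated as weakly identified in this machinery.
* The exploring agent's lapse is not part of the fitted models, so fits to
  autonomous-explorer cohorts are deliberately misspecified; recovery
  studies use the schedule-following generator instead.
* Response times are carried through the session format but never
  modelled; haemodynamic convolution of the exported regressors is out of
  scope.

## Problem sizes

Cohort-level tests use 50 sessions for parameter recovery, 30 for model
recovery and for the exploration statistics, 12 for the fixed-policy
search comparison, and 100 seeded agents per policy for the performance
ordering; the chance-level null uses the full 100,000 simulations. The
exhaustive HMM oracle is checked at $T \le 8$ ($7^8 \approx 5.8$ million
paths).
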