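# polexplore

Trial-by-trial computational modelling of how people explore *feature
dimensions* while learning values in an uninstructed multi-dimensional
reward task — for behavioural and model-based-neuroimaging researchers who
fit reinforcement-learning models to choice data.

## The problem and the models

In the task, each of 256 trials shows one of 8 stimuli combining three
binary features (shape, colour, pattern); the subject *goes* (gamble) or
*passes* (0 points). Two "all-match" stimuli always pay +10 on a go, the
two pattern non-match stimuli always pay −10, the other four pay ±10 at
50%. Nothing is instructed, so subjects must discover which features
matter while learning what the stimuli are worth.

The package implements, over the seven candidate policies π₁…π₇ (the
non-empty feature subsets):

* **Per-policy value learning** — delta rule
  `Q ← Q + α(R − Q)` with softmax choice
  `p(a) ∝ exp(βQ(s,a))`, session likelihood `L = Π p(Cₜ | D₁:ₜ₋₁, Θ)`.
* **Two policy-search models** inferring which policy is in use each trial:
  a *softmax-based* model (temporally independent, policy probability
  ∝ `exp(Q_i(sₜ, aₜ))`) and an *HMM-based* forward filter with a sticky
  transition matrix. Probability trajectories are smoothed by a degree-5
  OLS polynomial before the per-trial argmax that defines the current
  policy; policy *transitions* are change points of that series, and
  *cognitive ambiguity* is the posterior entropy
  `H(π) = −Σ P(πᵢ) log P(πᵢ)`.
* **Value-transfer learning** — a single active policy per trial whose
  table, at each transition, is either zeroed or *inherited* (copied on a
  dimensionality increase, fibre-averaged otherwise), plus a
  "policy 7 + ε" lapse baseline.
* **Inference** — deterministic multi-start maximum likelihood, AIC/BIC
  comparison, paired cohort tests, entropy/exploration statistics, and
  parameter/model-recovery harnesses on a fully manifested synthetic-agent
  cohort (no human data ship with the package).
* **Regressor export** — the four unconvolved parametric signals (value,
  reward prediction error, entropy, transition indicator) used by
  downstream neuroimaging GLMs.

## Worked example

```r
library(polexplore)

cfg <- task_config()                      # 8 stages x 32 trials, pattern rule

# chance-level screening cutoff from 100,000 random-responder sessions
chance_level_cutoff(cfg, n_sims = 100000, quantile = 0.95, seed = 20)
#> [1] 160

# simulate one exploring agent and analyse its session
sim <- simulate_cohort(list(agent_config("exploring_transfer", seed = 5003)), cfg)
trials <- sim$sessions[[1]]
stage1 <- lapply(1:7, function(i) fit_policy(trials, get_policy(i)))
rl     <- lapply(1:7, function(i) run_naive_rl(trials, get_policy(i), stage1[[i]]$params))
search <- run_policy_search(trials, rl, "softmax")
search$strategy
#> [1] "only_2d"
nrow(search$transitions)                  # detected policy transitions
#> [1] 6

# value-transfer fit with the searched schedule frozen
fit <- fit_model(trials, "transfer_inherited",
                 schedule = search$current_policy)
fit
#> <model_fit> transfer_inherited: logL = -125.48, k = 2, n = 256, AIC = 254.96, BIC = 262.05
```

The cutoff (160 points) is the 95th percentile of the coin-flip null whose
analytic SD is 98 points; sessions scoring above it beat chance at p < .05.
The fitted transfer model reports its shared learning rate and inverse
temperature (`fit$params`), and AIC/BIC for comparison against the zero-
initialisation and policy-search models via `compare_models()`.

The numbered scripts under `analysis/` run the full study on the synthetic
cohort: `01_simulate_cohort.R` (29 agents mirroring the study's group
structure, plus the chance cutoff), `02_policy_search.R` (per-policy fits,
both search models, strategies), `03_model_fits.R` (all five models, cohort
comparison tables), `04_exploration_stats.R` (entropy at transitions,
transition timing, likelihood–performance correlation),
`05_recovery.R` (parameter and model recovery) and
`06_export_regressors.R`. Each writes TSV tables under `results/`.

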