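# Independent oracles and small fixtures used across test files.

# Exhaustive-path oracle for the sticky-HMM forward filter: enumerates all
# 7^T policy paths, weighting each by uniform prior x transition products x
# emission products. Returns the filtered posterior at time T (sum of path
# weights grouped by final state, normalised) and the total path weight
# (the joint likelihood of the emissions).
hmm_path_oracle <- function(emissions, stay_prob) {
  T_len <- nrow(emissions)
  off <- (1 - stay_prob) / 6
  paths <- as.matrix(expand.grid(rep(list(1:7), T_len)))
  w <- rep(1 / 7, nrow(paths)) * emissions[1L, paths[, 1L]]
  if (T_len > 1L) {
    for (t in 2:T_len) {
      trans <- ifelse(paths[, t] == paths[, t - 1L], stay_prob, off)
      w <- w * trans * emissions[t, paths[, t]]
    }
  }
  post <- vapply(1:7, function(s) sum(w[paths[, T_len] == s]), numeric(1))
  list(posterior = post / sum(post), likelihood = sum(w))
}

# A minimal well-formed session data frame with all-match stimuli, used when
# only the trial scaffolding matters.
toy_session <- function(actions, rewards = NULL,
                        shape = "square", colour = "blue",
                        pattern = "vertical") {
  n <- length(actions)
  if (is.null(rewards)) {
    rewards <- ifelse(actions == "go", 10, 0)
  }
  data.frame(trial_index = seq_len(n), stage = rep(1L, n),
             shape = rep_len(shape, n), colour = rep_len(colour, n),
             pattern = rep_len(pattern, n),
             action = actions, reward = rewards,
             response_time = NA_real_, stringsAsFactors = FALSE)
}

# One simulated session from a seeded agent, for tests needing realistic
# trial structure.
sim_session <- function(kind = "fixed_policy", seed = 1L, policy_id = 7L,
                        alpha = 0.25, beta = 5, ...) {
  cfg <- task_config()
  sim <- simulate_cohort(list(agent_config(kind, seed = seed,
                                           policy_id = policy_id,
                                           alpha = alpha, beta = beta, ...)),
                         cfg)
  sim$sessions[[1L]]
}

# Emission matrix (T x 7) built from per-policy choice probabilities of a
# session prefix, matching what the HMM filter consumes.
emissions_for <- function(trials, rl_list) {
  pmax(vapply(rl_list, function(r) r$p_action, numeric(nrow(trials))), 1e-12)
}
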