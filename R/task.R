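#' @keywords internal
"_PACKAGE"

# Feature dimensions and their binary level encodings. Level 0 is always the
# level belonging to the first rewarded ("all-match") stimulus, so the two
# all-match stimuli are (0,0,0) and (1,1,1) in every rule variant.
FEATURES <- c("shape", "colour", "pattern")

FEATURE_LEVELS <- list(
  shape   = c(square = 0L, circle = 1L),
  colour  = c(blue = 0L, yellow = 1L),
  pattern = c(vertical = 0L, horizontal = 1L)
)

RULE_VARIANTS <- c("pattern_nonmatch", "shape_nonmatch", "colour_nonmatch")

#' Convert feature labels to their 0/1 level codes
#'
#' @param x character vector of labels for one feature dimension.
#' @param feature one of `"shape"`, `"colour"`, `"pattern"`.
#' @return integer vector of 0/1 levels.
#' @keywords internal
feature_level <- function(x, feature) {
  codes <- FEATURE_LEVELS[[feature]]
  out <- unname(codes[as.character(x)])
  if (anyNA(out)) {
    stop(sprintf("invalid %s label(s): %s", feature,
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

feature_label <- function(level, feature) {
  names(FEATURE_LEVELS[[feature]])[level + 1L]
}

#' Task configuration
#'
#' Defines one experiment's reward rule and trial structure. The main task is
#' 8 stages of 32 trials (256 trials); the behavioural variant experiment has
#' 10 stages (320 trials) and may penalise the shape or colour non-match pair
#' instead of the pattern non-match pair.
#'
#' @param rule_variant which non-match pair is deterministically penalised:
#'   `"pattern_nonmatch"` (main task), `"shape_nonmatch"` or
#'   `"colour_nonmatch"`.
#' @param n_stages number of stages (default 8; the variant experiment uses 10).
#' @param trials_per_stage trials per stage (default 32).
#' @param reward_magnitude absolute reward in points (default 10).
#' @param random_reward_prob probability that a "go" on a random-category
#'   stimulus wins rather than loses (default 0.5).
#' @param seed optional integer seed used by [generate_trial_sequence()].
#' @return a list of class `task_config`.
#' @export
task_config <- function(rule_variant = "pattern_nonmatch",
                        n_stages = 8L,
                        trials_per_stage = 32L,
                        reward_magnitude = 10,
                        random_reward_prob = 0.5,
                        seed = NULL) {
  rule_variant <- match.arg(rule_variant, RULE_VARIANTS)
  stopifnot(n_stages >= 1L, trials_per_stage >= 1L,
            reward_magnitude > 0,
            random_reward_prob >= 0, random_reward_prob <= 1)
  n_trials <- n_stages * trials_per_stage
  if (n_trials %% 8L != 0L) {
    stop("total trial count must be divisible by 8 (one slot per stimulus)")
  }
  structure(list(rule_variant = rule_variant,
                 n_stages = as.integer(n_stages),
                 trials_per_stage = as.integer(trials_per_stage),
                 reward_magnitude = reward_magnitude,
                 random_reward_prob = random_reward_prob,
                 seed = seed),
            class = "task_config")
}

# For a non-all-match stimulus, the single dimension in which it differs from
# the nearest all-match stimulus (every non-match stimulus is Hamming-1 from
# exactly one of the two all-match stimuli).
nonmatch_dimension <- function(levels) {
  s <- sum(levels)
  if (s == 0L || s == 3L) return(NA_character_)
  if (s == 1L) FEATURES[which(levels == 1L)] else FEATURES[which(levels == 0L)]
}

#' Enumerate the eight task stimuli and their reward categories
#'
#' Each stimulus combines a binary shape, colour and pattern. The two
#' "all-match" stimuli (blue-square-vertical, yellow-circle-horizontal) are
#' always worth +10 on a go; the pair that differs from an all-match stimulus
#' only in the variant's named dimension is always worth -10; the remaining
#' four stimuli pay +10 or -10 with equal probability.
#'
#' @param rule_variant see [task_config()].
#' @return a data frame with one row per stimulus: `shape`, `colour`,
#'   `pattern` (labels) and `category`.
#' @examples
#' enumerate_stimuli("pattern_nonmatch")
#' @export
enumerate_stimuli <- function(rule_variant = "pattern_nonmatch") {
  rule_variant <- match.arg(rule_variant, RULE_VARIANTS)
  penal_dim <- sub("_nonmatch$", "", rule_variant)
  random_dims <- setdiff(FEATURES, penal_dim)
  grid <- expand.grid(shape = 0:1, colour = 0:1, pattern = 0:1,
                      KEEP.OUT.ATTRS = FALSE)
  category <- character(8L)
  for (i in seq_len(8L)) {
    lv <- as.integer(grid[i, FEATURES])
    nd <- nonmatch_dimension(lv)
    category[i] <-
      if (is.na(nd)) "all_match"
      else if (nd == penal_dim) "penalised_nonmatch"
      else if (nd == random_dims[1L]) "random_nonmatch_A"
      else "random_nonmatch_B"
  }
  data.frame(shape = feature_label(grid$shape, "shape"),
             colour = feature_label(grid$colour, "colour"),
             pattern = feature_label(grid$pattern, "pattern"),
             category = category,
             stringsAsFactors = FALSE)
}

#' Reward category of a single stimulus
#' @param stimulus named list / one-row data frame with `shape`, `colour`,
#'   `pattern` labels.
#' @param rule_variant see [task_config()].
#' @return one of `"all_match"`, `"penalised_nonmatch"`,
#'   `"random_nonmatch_A"`, `"random_nonmatch_B"`.
#' @export
stimulus_category <- function(stimulus, rule_variant = "pattern_nonmatch") {
  stims <- enumerate_stimuli(rule_variant)
  hit <- stims$shape == stimulus$shape &
    stims$colour == stimulus$colour &
    stims$pattern == stimulus$pattern
  if (sum(hit) != 1L) stop("stimulus does not match a task stimulus")
  stims$category[hit]
}

#' Sample the reward for one choice
#'
#' Pass always earns 0. Go earns +magnitude on an all-match stimulus,
#' -magnitude on a penalised non-match stimulus, and +/-magnitude at the
#' configured probability otherwise. Uses the current RNG state.
#'
#' @param stimulus as in [stimulus_category()].
#' @param action `"go"` or `"pass"`.
#' @param config a [task_config()].
#' @return reward in points.
#' @export
sample_reward <- function(stimulus, action, config) {
  if (!action %in% c("go", "pass")) {
    stop("action must be 'go' or 'pass' (missed trials carry no reward draw)")
  }
  if (action == "pass") return(0)
  m <- config$reward_magnitude
  switch(stimulus_category(stimulus, config$rule_variant),
         all_match = m,
         penalised_nonmatch = -m,
         if (stats::runif(1) < config$random_reward_prob) m else -m)
}

#' Generate a balanced, shuffled stimulus sequence
#'
#' Each of the 8 stimuli appears exactly `n_trials / 8` times; the order is a
#' seeded uniform shuffle, matching a design in which all trials are presented
#' in random order with uniform exposure to the reward rule.
#'
#' @param config a [task_config()]; its `seed` (if non-NULL) seeds the shuffle.
#' @return data frame of `n_stages * trials_per_stage` stimulus rows with
#'   `trial_index`, `stage`, `shape`, `colour`, `pattern`, `category`.
#' @export
generate_trial_sequence <- function(config) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_stages * config$trials_per_stage
  stims <- enumerate_stimuli(config$rule_variant)
  idx <- sample(rep(seq_len(8L), each = n / 8L))
  out <- stims[idx, , drop = FALSE]
  out$trial_index <- seq_len(n)
  out$stage <- rep(seq_len(config$n_stages), each = config$trials_per_stage)
  rownames(out) <- NULL
  out[, c("trial_index", "stage", "shape", "colour", "pattern", "category")]
}

#' Play one session with an agent
#'
#' The agent must expose `choose(stimulus) -> "go"|"pass"` and
#' `observe(stimulus, action, reward)`. One trial record is produced per
#' stimulus; the final score is the summed reward.
#'
#' @param agent an agent (see [random_agent()], [fixed_policy_agent()],
#'   [exploring_transfer_agent()]).
#' @param config a [task_config()].
#' @return list with `trials` (a session data frame, see [read_session()])
#'   and `final_score`.
#' @export
play_session <- function(agent, config) {
  seq_df <- generate_trial_sequence(config)
  n <- nrow(seq_df)
  stims <- enumerate_stimuli(config$rule_variant)
  # map each trial to its stimulus row for fast category lookup
  key <- paste(seq_df$shape, seq_df$colour, seq_df$pattern)
  skey <- paste(stims$shape, stims$colour, stims$pattern)
  cat_by_trial <- stims$category[match(key, skey)]
  m <- config$reward_magnitude

  action <- character(n)
  reward <- numeric(n)
  for (t in seq_len(n)) {
    stim <- as.list(seq_df[t, c("shape", "colour", "pattern")])
    a <- agent$choose(stim)
    if (!a %in% c("go", "pass")) {
      stop(sprintf("agent returned invalid action '%s' on trial %d", a, t))
    }
    r <- if (a == "pass") 0 else switch(cat_by_trial[t],
      all_match = m,
      penalised_nonmatch = -m,
      if (stats::runif(1) < config$random_reward_prob) m else -m)
    agent$observe(stim, a, r)
    action[t] <- a
    reward[t] <- r
  }
  trials <- data.frame(trial_index = seq_df$trial_index,
                       stage = seq_df$stage,
                       shape = seq_df$shape,
                       colour = seq_df$colour,
                       pattern = seq_df$pattern,
                       action = action,
                       reward = reward,
                       response_time = NA_real_,
                       stringsAsFactors = FALSE)
  list(trials = trials, final_score = sum(reward))
}

#' Chance-level score cutoff from a random-responder null
#'
#' Simulates sessions played by an agent that goes or passes with probability
#' 0.5 on every trial and returns an empirical quantile of the final-score
#' distribution. The score of such a session depends only on how many trials
#' of each reward category drew a "go", so sessions are sampled directly from
#' the category-count decomposition: with n/8 trials per stimulus the null
#' score is m*(B1 - B2) + m*(2*B3 - G), where B1, B2 ~ Binom(n/4, 1/2) are the
#' go-counts on the all-match and penalised stimuli and B3 ~ Binom(G, 1/2)
#' counts wins among the G ~ Binom(n/2, 1/2) go trials on random stimuli.
#'
#' @param config a [task_config()].
#' @param n_sims number of simulated sessions (the cohort screening null uses
#'   100,000).
#' @param quantile probability in (0,1); the screening cutoff is 0.95.
#' @param seed integer seed.
#' @return the empirical quantile of final scores, in points.
#' @export
chance_level_cutoff <- function(config, n_sims = 100000L, quantile = 0.95,
                                seed = NULL) {
  stopifnot(inherits(config, "task_config"), n_sims >= 1,
            quantile > 0, quantile < 1)
  if (!is.null(seed)) set.seed(seed)
  scores <- simulate_null_scores(config, n_sims)
  unname(stats::quantile(scores, probs = quantile))
}

# Vector of n_sims random-responder final scores (see chance_level_cutoff).
simulate_null_scores <- function(config, n_sims) {
  n <- config$n_stages * config$trials_per_stage
  m <- config$reward_magnitude
  p <- config$random_reward_prob
  n_det <- n / 4L       # trials on the 2 all-match (= 2 penalised) stimuli
  n_rand <- n / 2L      # trials on the 4 random-category stimuli
  go_plus <- stats::rbinom(n_sims, n_det, 0.5)
  go_minus <- stats::rbinom(n_sims, n_det, 0.5)
  go_rand <- stats::rbinom(n_sims, n_rand, 0.5)
  wins <- stats::rbinom(n_sims, go_rand, p)
  m * (go_plus - go_minus) + m * (2 * wins - go_rand)
}
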