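#' Agent constructors
#'
#' Agents are lists exposing `choose(stimulus) -> "go"/"pass"` and
#' `observe(stimulus, action, reward)`, with internal state held in a
#' closure; [play_session()] drives them through a session. All randomness
#' uses the current RNG stream, so a session is reproducible from the task
#' seed.
#'
#' `random_agent()` flips a fair coin on every trial and ignores feedback —
#' the null responder behind the chance-level cutoff.
#'
#' @return an agent list.
#' @export
random_agent <- function() {
  list(kind = "random",
       choose = function(stimulus) if (stats::runif(1) < 0.5) "go" else "pass",
       observe = function(stimulus, action, reward) invisible(NULL))
}

#' @rdname random_agent
#'
#' @description `fixed_policy_agent()` learns state-action values by the
#' delta rule on a single policy's state-space and chooses by the softmax
#' rule; it never changes policy.
#'
#' @param policy a `policy` from [get_policy()].
#' @param params a [learning_params()].
#' @export
fixed_policy_agent <- function(policy, params) {
  stopifnot(inherits(policy, "policy"), inherits(params, "learning_params"))
  q <- matrix(0, nrow = policy$n_states, ncol = 2L)
  choose <- function(stimulus) {
    s <- project_state(stimulus, policy)
    p <- softmax_choice_prob(q[s, 1L], q[s, 2L], params$beta)
    if (stats::runif(1) < p[["go"]]) "go" else "pass"
  }
  observe <- function(stimulus, action, reward) {
    s <- project_state(stimulus, policy)
    ai <- if (action == "go") 1L else 2L
    q[s, ai] <<- q[s, ai] + params$alpha * (reward - q[s, ai])
    invisible(NULL)
  }
  list(kind = "fixed_policy", policy = policy, params = params,
       choose = choose, observe = observe, q = function() q)
}

#' @rdname random_agent
#'
#' @description `exploring_transfer_agent()` acts via the softmax rule on a
#' single active policy (plus a small go-biased lapse, the curiosity presses
#' that keep information flowing), while learning background value tables for
#' all seven policies in parallel. Its subjective ambiguity on a trial is the
#' entropy of a posterior over policies proportional to
#' `exp(max_a Q_i(s_t, a) / ambiguity_temp)` — how clearly some policy knows
#' what the current stimulus is worth. When the mean ambiguity over the last
#' `entropy_window` trials exceeds `switch_threshold`, with probability
#' `switch_prob` the agent adopts a policy drawn proportional to the
#' window-averaged posterior and initialises the new active table by
#' `init_rule` ([transfer_initialise()]). This generative switching rule is
#' the package's own construction of entropy-driven exploration: it produces
#' frequent early transitions that thin out as values differentiate, and a
#' handful of transitions per 256-trial session.
#'
#' @param switch_threshold ambiguity level (nats) above which a switch
#'   becomes possible; default `0.8 * log(7)`.
#' @param switch_prob probability of switching on an eligible trial
#'   (default 0.1).
#' @param init_rule `"inherited"` or `"zero"` initialisation at switches.
#' @param start_policy id of the initial active policy (default 4, a
#'   two-feature policy, so inherited transfers exercise dimensionality
#'   increases).
#' @param ambiguity_temp temperature of the greedy-value posterior behind the
#'   ambiguity signal (default 2: a fifth of the reward magnitude, so fully
#'   learned values concentrate the posterior but single lucky rewards do
#'   not).
#' @param entropy_window number of recent trials averaged into the ambiguity
#'   signal (default 16; ambiguity is a slowly varying cognitive state, not a
#'   single-trial flicker).
#' @param lapse probability of an exploratory "go" press regardless of
#'   learned values (default 0.15).
#' @export
exploring_transfer_agent <- function(params,
                                     switch_threshold = 0.8 * log(7),
                                     switch_prob = 0.1,
                                     init_rule = c("inherited", "zero"),
                                     start_policy = 4L,
                                     ambiguity_temp = 2,
                                     entropy_window = 16L,
                                     lapse = 0.15) {
  init_rule <- match.arg(init_rule)
  stopifnot(inherits(params, "learning_params"),
            switch_threshold >= 0, switch_threshold <= log(7) + 1e-9,
            switch_prob >= 0, switch_prob <= 1,
            ambiguity_temp > 0, entropy_window >= 1L,
            lapse >= 0, lapse <= 1)
  policies <- enumerate_policies()
  bg <- lapply(policies, function(p) matrix(0, p$n_states, 2L))
  active <- as.integer(start_policy)
  q <- matrix(0, policies[[active]]$n_states, 2L)
  ent_hist <- numeric(0)
  post_hist <- matrix(numeric(0), 0L, 7L)
  switch_log <- integer(0)
  trial <- 0L

  choose <- function(stimulus) {
    s <- project_state(stimulus, policies[[active]])
    p <- softmax_choice_prob(q[s, 1L], q[s, 2L], params$beta)
    p_go <- (1 - lapse) * p[["go"]] + lapse
    if (stats::runif(1) < p_go) "go" else "pass"
  }
  observe <- function(stimulus, action, reward) {
    trial <<- trial + 1L
    ai <- if (action == "go") 1L else 2L
    # ambiguity posterior: each policy scored by its greedy value for the
    # current stimulus, from the pre-update background tables
    gv <- vapply(1:7, function(i) {
      max(bg[[i]][project_state(stimulus, policies[[i]]), ])
    }, numeric(1))
    z <- gv / ambiguity_temp
    e <- exp(z - max(z))
    post <- e / sum(e)
    ent_hist <<- c(ent_hist, policy_entropy(post))
    post_hist <<- rbind(post_hist, post)
    # delta-rule updates: active table and all background tables
    s <- project_state(stimulus, policies[[active]])
    q[s, ai] <<- q[s, ai] + params$alpha * (reward - q[s, ai])
    for (i in 1:7) {
      si <- project_state(stimulus, policies[[i]])
      bg[[i]][si, ai] <<- bg[[i]][si, ai] +
        params$alpha * (reward - bg[[i]][si, ai])
    }
    k <- max(1L, trial - entropy_window + 1L)
    if (mean(ent_hist[k:trial]) > switch_threshold &&
        stats::runif(1) < switch_prob) {
      mp <- colMeans(post_hist[k:trial, , drop = FALSE])
      new <- sample.int(7L, 1L, prob = mp)
      if (new != active) {
        q <<- transfer_initialise(q, policies[[active]], policies[[new]],
                                  init_rule)
        active <<- new
        switch_log <<- c(switch_log, trial)
      }
    }
    invisible(NULL)
  }
  list(kind = "exploring_transfer", params = params,
       init_rule = init_rule, switch_threshold = switch_threshold,
       switch_prob = switch_prob, ambiguity_temp = ambiguity_temp,
       entropy_window = entropy_window, lapse = lapse,
       choose = choose, observe = observe,
       active_policy = function() active,
       switches = function() switch_log)
}

#' @rdname random_agent
#'
#' @description `scheduled_transfer_agent()` is the value-transfer model run
#' generatively: it follows a prescribed per-trial policy schedule, learns by
#' the delta rule within the active policy, initialises each newly scheduled
#' policy by `init_rule`, and chooses by the softmax rule. It is the known
#' generator behind parameter- and model-recovery studies.
#'
#' @param schedule integer vector of per-trial policy ids.
#' @export
scheduled_transfer_agent <- function(schedule, params,
                                     init_rule = c("inherited", "zero")) {
  init_rule <- match.arg(init_rule)
  stopifnot(inherits(params, "learning_params"), length(schedule) >= 1L)
  policies <- enumerate_policies()
  active <- schedule[1L]
  q <- matrix(0, policies[[active]]$n_states, 2L)
  trial <- 0L
  advance <- function() {
    # the schedule position advances at choose(); transitions re-initialise
    trial <<- trial + 1L
    if (schedule[trial] != active) {
      q <<- transfer_initialise(q, policies[[active]],
                                policies[[schedule[trial]]], init_rule)
      active <<- schedule[trial]
    }
  }
  choose <- function(stimulus) {
    advance()
    s <- project_state(stimulus, policies[[active]])
    p <- softmax_choice_prob(q[s, 1L], q[s, 2L], params$beta)
    if (stats::runif(1) < p[["go"]]) "go" else "pass"
  }
  observe <- function(stimulus, action, reward) {
    s <- project_state(stimulus, policies[[active]])
    ai <- if (action == "go") 1L else 2L
    q[s, ai] <<- q[s, ai] + params$alpha * (reward - q[s, ai])
    invisible(NULL)
  }
  list(kind = "scheduled_transfer", params = params, init_rule = init_rule,
       schedule = schedule, choose = choose, observe = observe,
       q = function() q)
}

#' Generate an exploration-like policy schedule
#'
#' A per-trial policy schedule with a few transitions concentrated in the
#' early trials (matching the empirical pattern that exploration happens
#' while ambiguity is high), tending to move from lower- to
#' higher-dimensional policies.
#'
#' @param n_trials schedule length.
#' @param n_transitions number of policy changes (default 3).
#' @param seed integer seed.
#' @return integer vector of policy ids of length `n_trials`.
#' @export
make_exploration_schedule <- function(n_trials, n_transitions = 3L,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_trials >= 2L, n_transitions >= 0L)
  # early-biased change points
  times <- sort(unique(pmax(2L, pmin(n_trials, 1L +
    floor(stats::rbeta(n_transitions, 1.5, 4) * n_trials)))))
  dims <- policy_dimensionality()
  pols <- integer(length(times) + 1L)
  pols[1L] <- sample(c(1:6), 1L)   # start below the full policy
  for (j in seq_along(times)) {
    prev <- pols[j]
    higher <- setdiff(which(dims > dims[prev]), prev)
    cand <- if (length(higher) > 0L && stats::runif(1) < 0.7) higher
            else setdiff(1:7, prev)
    pols[j + 1L] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  out <- rep(pols[1L], n_trials)
  for (j in seq_along(times)) out[times[j]:n_trials] <- pols[j + 1L]
  out
}

#' Synthetic-agent configuration
#'
#' One row of a cohort recipe: which agent to build and every generator
#' parameter, so the manifest written by [simulate_cohort()] is sufficient to
#' reproduce the session bit-exactly.
#'
#' @param kind `"random"`, `"fixed_policy"` or `"exploring_transfer"`.
#' @param seed integer seed for the whole session (sequence, rewards,
#'   choices).
#' @param policy_id policy id for fixed-policy agents (and the start policy
#'   of exploring agents).
#' @param alpha,beta learning parameters (ignored by random agents).
#' @param init_rule,switch_threshold,switch_prob,ambiguity_temp,entropy_window,lapse
#'   exploring-agent settings, see [exploring_transfer_agent()].
#' @return list of class `agent_config`.
#' @export
agent_config <- function(kind = c("random", "fixed_policy",
                                  "exploring_transfer"),
                         seed,
                         policy_id = 4L,
                         alpha = 0.25, beta = 5,
                         init_rule = "inherited",
                         switch_threshold = 0.8 * log(7),
                         switch_prob = 0.1,
                         ambiguity_temp = 2,
                         entropy_window = 16L,
                         lapse = 0.15) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed),
                 policy_id = as.integer(policy_id),
                 alpha = alpha, beta = beta, init_rule = init_rule,
                 switch_threshold = switch_threshold,
                 switch_prob = switch_prob,
                 ambiguity_temp = ambiguity_temp,
                 entropy_window = as.integer(entropy_window),
                 lapse = lapse),
            class = "agent_config")
}

build_agent <- function(cfg) {
  switch(cfg$kind,
         random = random_agent(),
         fixed_policy = fixed_policy_agent(get_policy(cfg$policy_id),
                                           learning_params(cfg$alpha, cfg$beta)),
         exploring_transfer = exploring_transfer_agent(
           learning_params(cfg$alpha, cfg$beta),
           switch_threshold = cfg$switch_threshold,
           switch_prob = cfg$switch_prob,
           init_rule = cfg$init_rule,
           start_policy = cfg$policy_id,
           ambiguity_temp = cfg$ambiguity_temp,
           entropy_window = cfg$entropy_window,
           lapse = cfg$lapse))
}

#' Simulate a cohort of synthetic agents
#'
#' Plays one session per agent configuration, each fully determined by its
#' own seed, and returns the sessions together with a ground-truth manifest
#' recording every generator parameter (the reference for parameter- and
#' model-recovery studies). Optionally writes one session TSV per agent plus
#' `manifest.tsv` to a directory.
#'
#' @param configs list of [agent_config()]s with distinct seeds.
#' @param config a [task_config()] (its own `seed` field is ignored; each
#'   agent's seed governs its session).
#' @param dir optional output directory.
#' @return list with `sessions` (list of trial data frames), `scores`,
#'   and `manifest` (data frame).
#' @export
simulate_cohort <- function(configs, config, dir = NULL) {
  stopifnot(inherits(config, "task_config"))
  seeds <- vapply(configs, `[[`, integer(1), "seed")
  if (anyDuplicated(seeds)) stop("agent seeds must be distinct")
  sessions <- vector("list", length(configs))
  scores <- numeric(length(configs))
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    session_cfg <- config
    session_cfg$seed <- cfg$seed
    agent <- build_agent(cfg)
    res <- play_session(agent, session_cfg)
    sessions[[i]] <- res$trials
    scores[i] <- res$final_score
    rows[[i]] <- data.frame(agent_id = i, kind = cfg$kind,
                            policy = cfg$policy_id,
                            alpha = cfg$alpha, beta = cfg$beta,
                            init_rule = cfg$init_rule,
                            switch_threshold = cfg$switch_threshold,
                            switch_prob = cfg$switch_prob,
                            ambiguity_temp = cfg$ambiguity_temp,
                            entropy_window = cfg$entropy_window,
                            lapse = cfg$lapse,
                            seed = cfg$seed,
                            final_score = res$final_score,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) {
    manifest <- data.frame(agent_id = integer(0), kind = character(0),
                           policy = integer(0), alpha = numeric(0),
                           beta = numeric(0), init_rule = character(0),
                           switch_threshold = numeric(0),
                           switch_prob = numeric(0),
                           ambiguity_temp = numeric(0),
                           entropy_window = integer(0), lapse = numeric(0),
                           seed = integer(0), final_score = numeric(0))
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(sessions)) {
      write_session(sessions[[i]],
                    file.path(dir, sprintf("session_%03d.tsv", i)))
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(sessions = sessions, scores = scores, manifest = manifest)
}

#' A mixed cohort recipe mirroring the study's group structure
#'
#' 29 agents: 15 exploring agents that start on a two-feature policy
#' (dimension-increasing explorers), 4 that start on the full policy
#' (dimension reducers), 4 fixed three-feature learners, 2 fixed two-feature
#' learners and 4 random responders.
#'
#' @param seed base seed; agent i uses `seed * 1000 + i`.
#' @param alpha,beta learning parameters for all learning agents.
#' @return list of [agent_config()]s.
#' @export
mixed_cohort_configs <- function(seed = 1L, alpha = 0.25, beta = 5) {
  kinds <- c(rep("exploring_transfer", 15L),  # 2d start: explore upward
             rep("exploring_transfer", 4L),   # 3d start: may reduce
             rep("fixed_policy", 4L),         # 3d-only
             rep("fixed_policy", 2L),         # 2d-only
             rep("random", 4L))
  pol <- c(rep(4L, 15L), rep(7L, 4L), rep(7L, 4L), rep(4L, 2L), rep(7L, 4L))
  lapply(seq_along(kinds), function(i) {
    agent_config(kinds[i], seed = seed * 1000L + i, policy_id = pol[i],
                 alpha = alpha, beta = beta)
  })
}
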