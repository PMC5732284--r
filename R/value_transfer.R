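#' Initialise a newly adopted policy's value table
#'
#' At a policy transition the new policy's state-action table is either reset
#' to zero (relearn from scratch) or inherited from the previous policy's
#' learned values: each new state takes the unweighted mean of the previous
#' policy's values over the old states consistent with it on the features the
#' two policies share. When the new policy refines the old one
#' (dimensionality increase with nested features) exactly one old state is
#' consistent, so the mean degenerates to a direct copy; on dimensionality
#' decrease or a sideways move it averages the fibre of compatible states;
#' with no shared features it is the grand mean. Both action columns are
#' transferred.
#'
#' @param q_prev states x 2 value table of `policy_prev`.
#' @param policy_prev,policy_curr `policy` objects.
#' @param init_rule `"zero"` or `"inherited"`.
#' @return states x 2 value table for `policy_curr` (columns go, pass).
#' @export
transfer_initialise <- function(q_prev, policy_prev, policy_curr,
                                init_rule = c("inherited", "zero")) {
  init_rule <- match.arg(init_rule)
  stopifnot(inherits(policy_prev, "policy"), inherits(policy_curr, "policy"))
  if (nrow(q_prev) != policy_prev$n_states || ncol(q_prev) != 2L) {
    stop("q_prev does not match policy_prev's state-space")
  }
  q_new <- matrix(0, nrow = policy_curr$n_states, ncol = 2L,
                  dimnames = list(NULL, c("go", "pass")))
  if (init_rule == "zero") return(q_new)
  for (s in seq_len(policy_curr$n_states)) {
    compat <- state_preimage(policy_prev, policy_curr, s)
    q_new[s, ] <- colMeans(q_prev[compat, , drop = FALSE])
  }
  q_new
}

#' Run the value-transfer learning model over a session
#'
#' Single-active-policy delta-rule learning: on each trial only the scheduled
#' policy's value table is consulted and updated. Whenever the schedule
#' switches policy, the incoming policy's table is initialised per
#' `init_rule` (see [transfer_initialise()]) before that trial's choice
#' probability is computed. A single (alpha, beta) pair is shared across the
#' whole session.
#'
#' @param trials session data frame.
#' @param schedule integer vector of per-trial active policy ids (length =
#'   trial count), typically [run_policy_search()]`$current_policy`.
#' @param params a [learning_params()].
#' @param init_rule `"inherited"` or `"zero"`.
#' @return list with per-trial `p_go`, `p_action`, `q_chosen` (pre-update
#'   value of the taken action), `rpe` (reward minus `q_chosen`), the
#'   `schedule`, transition `trials` indices, and `logL`.
#' @export
run_value_transfer <- function(trials, schedule, params,
                               init_rule = c("inherited", "zero")) {
  init_rule <- match.arg(init_rule)
  stopifnot(inherits(params, "learning_params"),
            length(schedule) == nrow(trials))
  n <- nrow(trials)
  policies <- enumerate_policies()
  act <- encode_actions(trials$action)
  reward <- as.numeric(trials$reward)

  # run the learning kernel over maximal constant-policy segments,
  # re-initialising the value table at every segment boundary
  seg <- rle(as.integer(schedule))
  ends <- cumsum(seg$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  # full-length state indices, computed once per policy actually scheduled
  states_cache <- new.env(parent = emptyenv())
  states_for <- function(trials, id) {
    key <- as.character(id)
    if (is.null(states_cache[[key]])) {
      states_cache[[key]] <- project_states(trials, policies[[id]])
    }
    states_cache[[key]]
  }
  p_go <- rep(NA_real_, n)
  p_action <- rep(NA_real_, n)
  q_chosen <- rep(NA_real_, n)
  rpe <- rep(NA_real_, n)
  q <- matrix(0, nrow = policies[[seg$values[1L]]]$n_states, ncol = 2L)
  for (j in seq_along(seg$values)) {
    pol <- policies[[seg$values[j]]]
    if (j > 1L) {
      q <- transfer_initialise(q, policies[[seg$values[j - 1L]]], pol,
                               init_rule)
    }
    idx <- starts[j]:ends[j]
    states <- states_for(trials, pol$id)[idx]
    res <- rl_block(states, act[idx], reward[idx], q,
                    params$alpha, params$beta, FALSE)
    p_go[idx] <- res$p_go
    p_action[idx] <- res$p_action
    q_chosen[idx] <- res$q_chosen
    rpe[idx] <- res$rpe
    q <- res$q
  }
  list(p_go = p_go, p_action = p_action, q_chosen = q_chosen, rpe = rpe,
       schedule = schedule, transition_trials = starts[-1L],
       init_rule = init_rule,
       logL = session_log_likelihood(p_action, trials))
}

#' Run the "policy 7 + noise" baseline model
#'
#' Delta-rule learning on the full three-feature policy with a lapse rate:
#' the choice probability is `(1 - epsilon) * softmax + epsilon * 0.5`, i.e.
#' with probability epsilon the response is uniformly random.
#'
#' @param trials session data frame.
#' @param params a [learning_params()].
#' @param epsilon lapse probability in \[0, 1\].
#' @return list with `p_go`, `p_action`, `q_chosen`, `rpe` and `logL`.
#' @export
run_policy7_noise <- function(trials, params, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  rl <- run_naive_rl(trials, get_policy(7L), params)
  mix <- function(p) (1 - epsilon) * p + epsilon * 0.5
  p_go <- mix(rl$p_go)
  p_action <- mix(rl$p_action)
  list(p_go = p_go, p_action = p_action,
       q_chosen = rl$q_chosen, rpe = rl$rpe, epsilon = epsilon,
       logL = session_log_likelihood(p_action, trials))
}
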