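# Probability floor applied before taking logs in all likelihoods.
PROB_FLOOR <- 1e-12

#' Learning parameters
#'
#' @param alpha learning rate in \[0, 1\]: the weight on the reward prediction
#'   error in the delta-rule update.
#' @param beta inverse temperature >= 0: softmax steepness; higher values give
#'   more deterministic choices.
#' @param beta_max upper bound enforced on `beta` (fitting bound; generous
#'   because fitted inverse temperatures can be large and skewed).
#' @return list of class `learning_params`.
#' @export
learning_params <- function(alpha, beta, beta_max = 50) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]")
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > beta_max) {
    stop(sprintf("beta must be a single number in [0, %g]", beta_max))
  }
  structure(list(alpha = alpha, beta = beta), class = "learning_params")
}

#' Delta-rule (Rescorla-Wagner) value update
#'
#' `q_new = q_old + alpha * (reward - q_old)`: the chosen action's value moves
#' toward the obtained reward by a fraction `alpha` of the prediction error.
#'
#' @param q_old current value.
#' @param reward obtained reward.
#' @param alpha learning rate in \[0, 1\].
#' @return updated value.
#' @export
rw_update <- function(q_old, reward, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  q_old + alpha * (reward - q_old)
}

#' Softmax choice probabilities for the two actions
#'
#' `p(a) = exp(beta * Q_a) / sum_a' exp(beta * Q_a')`, computed with
#' max-subtraction so large `beta * Q` cannot overflow.
#'
#' @param q_go,q_pass action values.
#' @param beta inverse temperature >= 0.
#' @return named numeric vector `c(go = p_go, pass = p_pass)`.
#' @export
softmax_choice_prob <- function(q_go, q_pass, beta) {
  if (beta < 0) stop("beta must be >= 0")
  z <- beta * c(unname(q_go), unname(q_pass))
  e <- exp(z - max(z))
  p <- unname(e / sum(e))
  c(go = p[1L], pass = p[2L])
}

#' Run delta-rule learning over a session under one policy
#'
#' Values start at zero. On each responded trial the choice probability of the
#' taken action is computed from the pre-update values via the softmax rule,
#' then the chosen action's value for the projected state is updated with the
#' observed reward. Missed trials are skipped entirely (no update; `NA`
#' probabilities).
#'
#' @param trials session data frame (see [read_session()]).
#' @param policy a `policy` from [get_policy()].
#' @param params a [learning_params()].
#' @return list with per-trial vectors `p_go`, `p_action` (probability of the
#'   action actually taken), `q_chosen` (pre-update value of the taken
#'   action), `rpe` (reward minus `q_chosen`; `NA` on missed trials), the
#'   final `q` table (states x actions), and `q_traj`, the pre-update value
#'   table trajectory as a `trials x states x 2` array (actions go, pass).
#' @export
run_naive_rl <- function(trials, policy, params) {
  stopifnot(inherits(policy, "policy"), inherits(params, "learning_params"))
  states <- project_states(trials, policy)
  act <- encode_actions(trials$action)
  res <- rl_block(states, act, as.numeric(trials$reward),
                  matrix(0, policy$n_states, 2L),
                  params$alpha, params$beta, TRUE)
  q <- res$q
  dimnames(q) <- list(NULL, c("go", "pass"))
  list(p_go = res$p_go, p_action = res$p_action, q_chosen = res$q_chosen,
       rpe = res$rpe, q = q, q_traj = res$q_traj,
       states = states, policy = policy)
}

# go = 1, pass = 2, missed = 0 (skipped by the learning kernel)
encode_actions <- function(action) {
  act <- match(action, c("go", "pass"))
  act[is.na(act)] <- 0L
  act
}

#' Session log-likelihood from per-trial choice probabilities
#'
#' Sum of log probabilities of the observed actions over responded trials
#' (the likelihood is a product of one-step conditional choice probabilities).
#' Probabilities are floored at `1e-12` before the log.
#'
#' @param p_action per-trial probability of the action actually taken (`NA`
#'   on missed trials).
#' @param trials the session the probabilities belong to (used to exclude
#'   missed trials).
#' @return log-likelihood (<= 0).
#' @export
session_log_likelihood <- function(p_action, trials) {
  if (length(p_action) != nrow(trials)) {
    stop("p_action length does not match trial count")
  }
  valid <- trials$action != "missed"
  p <- p_action[valid]
  if (anyNA(p)) stop("NA choice probability on a responded trial")
  sum(log(pmax(p, PROB_FLOOR)))
}

#' Run delta-rule learning under all seven policies
#'
#' Convenience wrapper producing the seven per-policy [run_naive_rl()]
#' outputs on the same session, optionally with policy-specific parameters.
#'
#' @param trials session data frame.
#' @param params either one [learning_params()] shared by all policies or a
#'   list of 7 of them (one per policy id).
#' @return list of 7 `run_naive_rl` results, indexed by policy id.
#' @export
run_all_policies <- function(trials, params) {
  if (inherits(params, "learning_params")) params <- rep(list(params), 7L)
  stopifnot(length(params) == 7L)
  lapply(1:7, function(i) run_naive_rl(trials, get_policy(i), params[[i]]))
}
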