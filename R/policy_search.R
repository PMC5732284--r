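#' Shannon entropy of a policy probability vector
#'
#' Natural-log entropy with the convention `0 * log(0) = 0`. For seven
#' policies the entropy lies in `[0, log(7)]`; high values mean the data do
#' not single out a policy (high cognitive ambiguity).
#'
#' @param p probability vector, or a matrix of per-trial probability rows.
#' @return entropy in nats (one value per row for matrix input).
#' @export
policy_entropy <- function(p) {
  if (is.matrix(p)) return(apply(p, 1L, policy_entropy))
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop("p must be a probability vector")
  }
  p <- pmax(p, 0)
  -sum(ifelse(p > 0, p * log(p), 0))
}

# Extract the T x 7 matrix of a per-policy per-trial field from a
# run_all_policies() result.
policy_matrix <- function(rl_list, field) {
  vapply(rl_list, function(r) r[[field]], numeric(length(rl_list[[1L]][[field]])))
}

#' Softmax-based policy posterior
#'
#' Treats the seven per-trial policy probabilities as temporally independent:
#' on each responded trial, the probability of policy i is proportional to
#' `exp(Q_i(s_t, a_t) / temperature)`, where `Q_i(s_t, a_t)` is the value
#' policy i assigned (before updating) to the action actually taken. Missed
#' trials carry the previous posterior forward (uniform before the first
#' responded trial).
#'
#' @param trials session data frame.
#' @param rl_list output of [run_all_policies()] on the same session.
#' @param temperature softmax-search temperature (fixed, default 1; not a
#'   fitted parameter).
#' @return list with `posterior` (trials x 7 matrix) and `entropy` (per-trial
#'   nats).
#' @export
softmax_policy_posterior <- function(trials, rl_list, temperature = 1) {
  stopifnot(length(rl_list) == 7L, temperature > 0)
  n <- nrow(trials)
  qa <- policy_matrix(rl_list, "q_chosen")      # n x 7, NA on missed trials
  post <- matrix(NA_real_, n, 7L)
  prev <- rep(1 / 7, 7L)
  for (t in seq_len(n)) {
    if (trials$action[t] == "missed") {
      post[t, ] <- prev
    } else {
      z <- qa[t, ] / temperature
      e <- exp(z - max(z))
      post[t, ] <- e / sum(e)
      prev <- post[t, ]
    }
  }
  list(posterior = post, entropy = policy_entropy(post))
}

#' HMM-based policy posterior (forward filter)
#'
#' Treats the policy in use as a hidden state evolving with a sticky
#' transition matrix (`stay_prob` on the diagonal, the rest spread evenly
#' over the other six policies). The filter starts from a uniform prior; each
#' responded trial's emission is the probability each policy's softmax rule
#' assigns to the action actually taken. `posterior` is the filtered
#' distribution after seeing the trial's choice; `predictive` is the
#' transition-propagated distribution before it, whose per-trial mixture
#' likelihoods multiply to the exact joint likelihood over all policy paths.
#' Missed trials carry both distributions forward unchanged.
#'
#' @param trials session data frame.
#' @param rl_list output of [run_all_policies()].
#' @param stay_prob self-transition probability, in (1/7, 1); default 0.9
#'   (fixed, not fitted).
#' @return list with `posterior`, `predictive` (trials x 7 matrices) and
#'   `entropy` of the filtered posterior.
#' @export
hmm_policy_posterior <- function(trials, rl_list, stay_prob = 0.9) {
  stopifnot(length(rl_list) == 7L, stay_prob > 1 / 7, stay_prob < 1)
  n <- nrow(trials)
  em <- pmax(policy_matrix(rl_list, "p_action"), PROB_FLOOR)  # n x 7
  off <- (1 - stay_prob) / 6
  post <- matrix(NA_real_, n, 7L)
  pred <- matrix(NA_real_, n, 7L)
  cur <- rep(1 / 7, 7L)   # predictive at t = 1: the uniform prior
  for (t in seq_len(n)) {
    pred[t, ] <- cur
    if (trials$action[t] == "missed") {
      post[t, ] <- cur
      next
    }
    w <- cur * em[t, ]
    tot <- sum(w)
    if (!is.finite(tot) || tot <= 0) stop("zero emission mass at trial ", t)
    post[t, ] <- w / tot
    # propagate through the sticky transition matrix
    cur <- stay_prob * post[t, ] + off * (1 - post[t, ])
  }
  list(posterior = post, predictive = pred,
       entropy = policy_entropy(post))
}

#' Polynomial smoothing of policy probability trajectories
#'
#' Fits an ordinary least-squares polynomial (default degree 5) in trial
#' index, rescaled to `[0, 1]`, to each policy's probability series. Smoothing
#' suppresses trial-to-trial noise before the per-trial argmax that defines
#' the current policy; the fitted curves are not renormalised or clipped.
#'
#' @param posterior trials x 7 posterior matrix.
#' @param degree polynomial degree (default 5).
#' @return trials x 7 matrix of fitted curves.
#' @export
smooth_posterior <- function(posterior, degree = 5L) {
  n <- nrow(posterior)
  if (n < degree + 1L) {
    stop(sprintf("need at least %d trials for a degree-%d polynomial",
                 degree + 1L, degree))
  }
  x <- if (n > 1L) (seq_len(n) - 1) / (n - 1) else 0
  X <- stats::poly(x, degree = degree, raw = FALSE)
  out <- apply(posterior, 2L, function(y)
    unname(stats::fitted(stats::lm(y ~ X))))
  dimnames(out) <- NULL
  out
}

#' Per-trial current policy from smoothed probability curves
#'
#' The policy with the highest smoothed probability on each trial is taken as
#' the one currently in use. Exact ties are broken toward lower
#' dimensionality, then lower policy id.
#'
#' @param smoothed trials x 7 matrix from [smooth_posterior()].
#' @return integer vector of policy ids, one per trial.
#' @export
current_policy <- function(smoothed) {
  dims <- policy_dimensionality()
  unname(apply(smoothed, 1L, function(row) {
    cand <- which(row == max(row))
    cand[order(dims[cand], cand)][1L]
  }))
}

#' Detect policy transition trials
#'
#' A transition occurs at every trial whose current policy differs from the
#' previous trial's.
#'
#' @param cp integer vector of per-trial current policy ids.
#' @return data frame with `trial_index`, `from_policy`, `to_policy` (zero
#'   rows when the series is constant).
#' @export
detect_transitions <- function(cp) {
  if (length(cp) < 2L) stop("current-policy series must have >= 2 trials")
  idx <- which(diff(cp) != 0L) + 1L
  data.frame(trial_index = idx,
             from_policy = cp[idx - 1L],
             to_policy = cp[idx])
}

#' Classify a session's exploration strategy
#'
#' Compares the modal policy dimensionality over the first and last quarters
#' of trials: `2d_to_3d` (dimensionality increased from two to three),
#' `3d_to_2d`, `only_2d`, `only_3d`; sessions dominated by a one-dimensional
#' policy are `one_dim`, anything else `other`.
#'
#' @param cp integer vector of per-trial current policy ids.
#' @return one of `"2d_to_3d"`, `"3d_to_2d"`, `"only_2d"`, `"only_3d"`,
#'   `"one_dim"`, `"other"`.
#' @export
classify_strategy <- function(cp) {
  if (length(cp) == 0L) stop("empty current-policy series")
  dims <- policy_dimensionality()[cp]
  modal <- function(x) as.integer(names(which.max(table(x))))
  if (modal(dims) == 1L) return("one_dim")
  q <- max(1L, length(cp) %/% 4L)
  d1 <- modal(dims[seq_len(q)])
  d2 <- modal(dims[seq.int(length(cp) - q + 1L, length(cp))])
  if (d1 == 2L && d2 == 3L) "2d_to_3d"
  else if (d1 == 3L && d2 == 2L) "3d_to_2d"
  else if (d1 == 2L && d2 == 2L) "only_2d"
  else if (d1 == 3L && d2 == 3L) "only_3d"
  else "other"
}

#' Session log-likelihood of a policy-mixture model
#'
#' Per responded trial, the model's probability of the observed choice is the
#' posterior-weighted mixture `sum_i P_t(pi_i) * p_i(C_t)` of the per-policy
#' choice probabilities; the log-likelihood sums the floored logs. For the
#' HMM model pass the `predictive` matrix so the product equals the exact
#' joint likelihood over policy paths.
#'
#' @param posterior trials x 7 matrix of policy probabilities.
#' @param rl_list output of [run_all_policies()].
#' @param trials session data frame.
#' @return log-likelihood (<= 0).
#' @export
mixture_session_likelihood <- function(posterior, rl_list, trials) {
  pa <- policy_matrix(rl_list, "p_action")
  if (nrow(posterior) != nrow(trials) || nrow(pa) != nrow(trials)) {
    stop("posterior / choice-probability rows do not match trial count")
  }
  valid <- trials$action != "missed"
  p <- rowSums(posterior * pa)[valid]
  sum(log(pmax(p, PROB_FLOOR)))
}

#' Full policy-search pass over one session
#'
#' Runs a posterior model (softmax or HMM), smooths it, extracts the
#' per-trial current policy, transitions, entropy and strategy class.
#'
#' @param trials session data frame.
#' @param rl_list output of [run_all_policies()].
#' @param method `"softmax"` or `"hmm"`.
#' @param temperature,stay_prob,degree see [softmax_policy_posterior()],
#'   [hmm_policy_posterior()], [smooth_posterior()].
#' @return list with `posterior`, `entropy`, `smoothed`, `current_policy`,
#'   `transitions`, `strategy`, `logL` (mixture likelihood) and, for the HMM,
#'   `predictive`.
#' @export
run_policy_search <- function(trials, rl_list, method = c("softmax", "hmm"),
                              temperature = 1, stay_prob = 0.9, degree = 5L) {
  method <- match.arg(method)
  ps <- if (method == "softmax") {
    softmax_policy_posterior(trials, rl_list, temperature)
  } else {
    hmm_policy_posterior(trials, rl_list, stay_prob)
  }
  sm <- smooth_posterior(ps$posterior, degree)
  cp <- current_policy(sm)
  lik_post <- if (method == "hmm") ps$predictive else ps$posterior
  c(ps, list(smoothed = sm,
             current_policy = cp,
             transitions = detect_transitions(cp),
             strategy = classify_strategy(cp),
             logL = mixture_session_likelihood(lik_post, rl_list, trials),
             method = method))
}
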