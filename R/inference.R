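#' Information criteria
#'
#' `aic = 2k - 2 logL`; `bic = k log(n) - 2 logL`. Lower is better; `n` is
#' the number of responded trials entering the likelihood.
#'
#' @param logL maximised log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (valid trials).
#' @return criterion value.
#' @export
aic <- function(logL, k) 2 * k - 2 * logL

#' @rdname aic
#' @export
bic <- function(logL, k, n) {
  stopifnot(n >= 1)
  k * log(n) - 2 * logL
}

# Deterministic multi-start maximisation of fn(alpha, beta[, extra]) over a
# coarse grid followed by bounded local refinement of the best starts.
# fn takes a parameter vector on the natural scale and returns a logL.
maximise_logl <- function(fn, lower, upper, starts, n_restarts = 3L) {
  neg <- function(par) {
    v <- fn(par)
    if (!is.finite(v)) 1e10 else -v
  }
  grid_vals <- apply(starts, 1L, neg)
  ord <- order(grid_vals)
  best <- NULL
  for (i in ord[seq_len(min(n_restarts, nrow(starts)))]) {
    res <- tryCatch(
      stats::optim(starts[i, ], neg, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    # fall back to the best grid point if every local search failed
    i <- ord[1L]
    best <- list(par = starts[i, ], value = grid_vals[i])
  }
  list(par = best$par, logL = -best$value)
}

# Default coarse grid over (alpha, beta): alpha evenly spaced, beta
# log-spaced. Extra columns (e.g. a lapse rate) are crossed in.
param_grid <- function(beta_max = 50, epsilon = FALSE) {
  alphas <- seq(0.05, 0.95, length.out = 5L)
  betas <- exp(seq(log(0.2), log(min(20, beta_max)), length.out = 5L))
  g <- as.matrix(expand.grid(alpha = alphas, beta = betas))
  if (epsilon) {
    g <- as.matrix(merge(as.data.frame(g),
                         data.frame(epsilon = c(0.05, 0.3, 0.6))))
    g <- g[, c("alpha", "beta", "epsilon")]
  }
  g
}

#' Fit one policy's learning parameters by maximum likelihood
#'
#' Maximises the session log-likelihood of [run_naive_rl()] under one policy
#' over (alpha, beta), using a deterministic coarse grid plus bounded local
#' refinement.
#'
#' @param trials session data frame.
#' @param policy a `policy`.
#' @param beta_max upper bound on the inverse temperature (default 50).
#' @param n_restarts number of grid starts refined locally (default 3).
#' @return list with `params` (a [learning_params()]) and `logL`.
#' @export
fit_policy <- function(trials, policy, beta_max = 50, n_restarts = 3L) {
  fn <- function(par) {
    rl <- run_naive_rl(trials, policy,
                       learning_params(par[1L], par[2L], beta_max))
    session_log_likelihood(rl$p_action, trials)
  }
  res <- maximise_logl(fn, lower = c(0, 1e-4), upper = c(1, beta_max),
                       starts = param_grid(beta_max), n_restarts = n_restarts)
  list(params = learning_params(res$par[1L], res$par[2L], beta_max),
       logL = res$logL)
}

MODEL_IDS <- c("naive_softmax_search", "naive_hmm_search",
               "transfer_zero", "transfer_inherited", "policy7_noise")

#' Fit a model to one session by maximum likelihood
#'
#' Implements the two-step estimation used throughout: the exploration
#' (search) models first fit each of the seven policies' (alpha, beta)
#' independently (14 free parameters) and score the session with the
#' posterior-mixture likelihood; the value-transfer models freeze the policy
#' schedule obtained from the softmax-based search and fit a single shared
#' (alpha, beta) (2 parameters); the policy-7 baseline adds a lapse rate
#' (3 parameters). All optimisation is a deterministic coarse grid plus
#' bounded local refinement, so refits reproduce exactly.
#'
#' @param trials session data frame.
#' @param model one of `"naive_softmax_search"`, `"naive_hmm_search"`,
#'   `"transfer_zero"`, `"transfer_inherited"`, `"policy7_noise"`.
#' @param schedule per-trial policy ids for the transfer models; when `NULL`
#'   it is derived via stage 1 + the softmax-based search.
#' @param stage1 optional precomputed list of 7 [fit_policy()] results
#'   (shared across models fitted to the same session).
#' @param beta_max,n_restarts see [fit_policy()].
#' @param temperature,stay_prob,degree search-model settings, see
#'   [run_policy_search()].
#' @return list of class `model_fit` with `model`, `params`, `logL`, `k`,
#'   `n`, `aic`, `bic` and model-specific extras (`stage1`, `schedule`,
#'   `epsilon`).
#' @export
fit_model <- function(trials, model = MODEL_IDS, schedule = NULL,
                      stage1 = NULL, beta_max = 50, n_restarts = 3L,
                      temperature = 1, stay_prob = 0.9, degree = 5L) {
  model <- match.arg(model)
  n_valid <- sum(trials$action != "missed")
  out <- list(model = model, n = n_valid)

  needs_stage1 <- model %in% c("naive_softmax_search", "naive_hmm_search") ||
    (is.null(schedule) && model %in% c("transfer_zero", "transfer_inherited"))
  if (needs_stage1 && is.null(stage1)) {
    stage1 <- lapply(1:7, function(i)
      fit_policy(trials, get_policy(i), beta_max, n_restarts))
  }

  if (model %in% c("naive_softmax_search", "naive_hmm_search")) {
    rl_list <- lapply(1:7, function(i)
      run_naive_rl(trials, get_policy(i), stage1[[i]]$params))
    method <- if (model == "naive_softmax_search") "softmax" else "hmm"
    search <- run_policy_search(trials, rl_list, method,
                                temperature = temperature,
                                stay_prob = stay_prob, degree = degree)
    out$params <- lapply(stage1, `[[`, "params")
    out$stage1 <- stage1
    out$search <- search
    out$logL <- search$logL
    out$k <- 14L
  } else if (model %in% c("transfer_zero", "transfer_inherited")) {
    if (is.null(schedule)) {
      rl_list <- lapply(1:7, function(i)
        run_naive_rl(trials, get_policy(i), stage1[[i]]$params))
      search <- run_policy_search(trials, rl_list, "softmax",
                                  temperature = temperature, degree = degree)
      schedule <- search$current_policy
      out$stage1 <- stage1
    }
    rule <- if (model == "transfer_inherited") "inherited" else "zero"
    fn <- function(par) {
      run_value_transfer(trials, schedule,
                         learning_params(par[1L], par[2L], beta_max),
                         rule)$logL
    }
    res <- maximise_logl(fn, lower = c(0, 1e-4), upper = c(1, beta_max),
                         starts = param_grid(beta_max),
                         n_restarts = n_restarts)
    out$params <- learning_params(res$par[1L], res$par[2L], beta_max)
    out$schedule <- schedule
    out$logL <- res$logL
    out$k <- 2L
  } else { # policy7_noise
    fn <- function(par) {
      run_policy7_noise(trials,
                        learning_params(par[1L], par[2L], beta_max),
                        par[3L])$logL
    }
    res <- maximise_logl(fn, lower = c(0, 1e-4, 0), upper = c(1, beta_max, 1),
                         starts = param_grid(beta_max, epsilon = TRUE),
                         n_restarts = n_restarts)
    out$params <- learning_params(res$par[1L], res$par[2L], beta_max)
    out$epsilon <- unname(res$par[3L])
    out$logL <- res$logL
    out$k <- 3L
  }
  out$aic <- aic(out$logL, out$k)
  out$bic <- bic(out$logL, out$k, out$n)
  structure(out, class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s: logL = %.2f, k = %d, n = %d, AIC = %.2f, BIC = %.2f\n",
              x$model, x$logL, x$k, x$n, x$aic, x$bic))
  invisible(x)
}

#' Extract a criterion from a list of fits
#' @param fits list of `model_fit` objects (one per session).
#' @param criterion `"aic"`, `"bic"` or `"logL"`.
#' @return numeric vector.
#' @export
fit_criterion <- function(fits, criterion = c("aic", "bic", "logL")) {
  criterion <- match.arg(criterion)
  vapply(fits, `[[`, numeric(1), criterion)
}

#' Paired comparison of two models across a cohort
#'
#' Paired two-sided t-test on per-session differences (model A minus model B)
#' of an information criterion; for AIC/BIC a negative mean difference means
#' model A fits better.
#'
#' @param fits_a,fits_b lists of `model_fit` objects for the same sessions,
#'   in the same order.
#' @param criterion `"aic"`, `"bic"` or `"logL"`.
#' @return list with `mean_diff`, `t`, `df`, `p`, `n`, and `degenerate`
#'   (TRUE when the differences have zero variance, where the t statistic is
#'   undefined).
#' @export
compare_models <- function(fits_a, fits_b, criterion = c("aic", "bic", "logL")) {
  criterion <- match.arg(criterion)
  if (length(fits_a) != length(fits_b)) {
    stop("cohorts are unpaired: different numbers of sessions")
  }
  d <- fit_criterion(fits_a, criterion) - fit_criterion(fits_b, criterion)
  n <- length(d)
  if (n < 2L) stop("need >= 2 paired sessions")
  if (stats::sd(d) == 0) {
    return(list(mean_diff = mean(d), t = NA_real_, df = n - 1L,
                p = if (mean(d) == 0) 1 else NA_real_,
                n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(mean_diff = mean(d), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, n = n, degenerate = FALSE)
}

#' Is entropy elevated at policy-transition trials?
#'
#' Per session, computes mean posterior entropy at transition trials minus
#' mean entropy over all trials, then tests the paired differences against
#' zero across sessions. Sessions without any transition contribute no
#' difference and are counted separately.
#'
#' @param sessions list, one element per session, each a list with `entropy`
#'   (per-trial nats) and `transitions` (a [detect_transitions()] data frame).
#' @return list with `mean_diff`, `t`, `df`, `p`, `n_included`, `n_excluded`.
#' @export
transition_entropy_test <- function(sessions) {
  diffs <- vapply(sessions, function(s) {
    idx <- s$transitions$trial_index
    if (length(idx) == 0L) return(NA_real_)
    mean(s$entropy[idx]) - mean(s$entropy)
  }, numeric(1))
  excluded <- sum(is.na(diffs))
  d <- diffs[!is.na(diffs)]
  if (length(d) < 2L) {
    stop("need >= 2 sessions with transitions for a cohort test")
  }
  if (stats::sd(d) == 0) {
    return(list(mean_diff = mean(d), t = NA_real_, df = length(d) - 1L,
                p = if (mean(d) == 0) 1 else NA_real_,
                n_included = length(d), n_excluded = excluded))
  }
  tt <- stats::t.test(d)
  list(mean_diff = mean(d), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       n_included = length(d), n_excluded = excluded)
}

#' Regression of entropy at transitions on trial index
#'
#' Pools every detected transition (across sessions) and regresses its
#' posterior entropy on its trial index by ordinary least squares. On
#' exploring cohorts transitions concentrate at early, high-entropy trials,
#' so the slope is expected negative.
#'
#' @param transitions data frame with columns `trial_index` and `entropy`,
#'   one row per pooled transition.
#' @return list with `slope`, `intercept`, `r_squared`, `p` (slope test),
#'   `n`.
#' @export
transition_timing_regression <- function(transitions) {
  stopifnot(all(c("trial_index", "entropy") %in% names(transitions)))
  if (nrow(transitions) < 3L) stop("need >= 3 pooled transitions")
  if (stats::sd(transitions$trial_index) == 0) {
    stop("degenerate regressor: all transitions at the same trial index")
  }
  fit <- stats::lm(entropy ~ trial_index, data = transitions)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2L, 4L]),
       n = nrow(transitions))
}

#' Correlation between model likelihood and task performance
#'
#' Ordinary least squares of final score on per-session model log-likelihood;
#' cohorts in which the model captures behaviour well show a positive slope
#' (better-explained participants earn more).
#'
#' @param logL per-session log-likelihoods.
#' @param scores per-session final scores, same order.
#' @return list with `slope`, `r_squared`, `p`, `n`.
#' @export
likelihood_performance_correlation <- function(logL, scores) {
  stopifnot(length(logL) == length(scores))
  if (stats::sd(scores) == 0 || stats::sd(logL) == 0) {
    return(list(slope = 0, r_squared = 0, p = 1, n = length(scores)))
  }
  fit <- stats::lm(scores ~ logL)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2L, 4L]),
       n = length(scores))
}
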