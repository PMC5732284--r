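SESSION_COLUMNS <- c("trial_index", "stage", "shape", "colour", "pattern",
                     "action", "reward", "response_time")

#' Read and write behavioural session files
#'
#' Sessions are tab-separated files with a header row and columns
#' `trial_index`, `stage`, `shape`, `colour`, `pattern`, `action`, `reward`,
#' `response_time` (seconds, `NA` when absent), one row per trial,
#' 1-based trial indices. Reading validates every row: feature labels must be
#' task levels, `action` must be go/pass/missed, pass and missed trials must
#' carry reward 0, and go trials must carry reward +/- `reward_magnitude`.
#' Writing and re-reading is lossless.
#'
#' @param path file path.
#' @param reward_magnitude expected absolute go reward (default 10).
#' @return `read_session()`: the validated session data frame.
#' @export
read_session <- function(path, reward_magnitude = 10) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_session(df, reward_magnitude)
}

#' @rdname read_session
#' @param trials session data frame.
#' @export
write_session <- function(trials, path, reward_magnitude = 10) {
  trials <- validate_session(trials, reward_magnitude)
  utils::write.table(trials[, SESSION_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_session
#' @export
validate_session <- function(trials, reward_magnitude = 10) {
  missing_cols <- setdiff(SESSION_COLUMNS, names(trials))
  if (length(missing_cols) > 0L) {
    stop("missing session column(s): ", paste(missing_cols, collapse = ", "))
  }
  fail <- function(row, col, msg) {
    stop(sprintf("session row %d, column '%s': %s", row, col, msg))
  }
  for (f in FEATURES) {
    bad <- which(!trials[[f]] %in% names(FEATURE_LEVELS[[f]]))
    if (length(bad) > 0L) {
      fail(bad[1L], f, paste("invalid label", trials[[f]][bad[1L]]))
    }
  }
  bad <- which(!trials$action %in% c("go", "pass", "missed"))
  if (length(bad) > 0L) fail(bad[1L], "action",
                             paste("invalid action", trials$action[bad[1L]]))
  no_go <- trials$action != "go"
  bad <- which(no_go & trials$reward != 0)
  if (length(bad) > 0L) {
    fail(bad[1L], "reward", "pass/missed trial must have reward 0")
  }
  bad <- which(!no_go & abs(trials$reward) != reward_magnitude)
  if (length(bad) > 0L) {
    fail(bad[1L], "reward",
         sprintf("go reward must be +/-%g", reward_magnitude))
  }
  if (!identical(as.integer(trials$trial_index), seq_len(nrow(trials)))) {
    stop("trial_index must run 1..n_trials")
  }
  trials$reward <- as.numeric(trials$reward)
  trials$response_time <- as.numeric(trials$response_time)
  trials
}

#' Export a policy-search posterior table
#'
#' TSV with per-trial policy probabilities, posterior entropy, the smoothed
#' argmax current policy and a transition indicator.
#'
#' @param search a [run_policy_search()] result.
#' @param path output file.
#' @return the exported data frame, invisibly.
#' @export
export_posterior <- function(search, path) {
  post <- search$posterior
  df <- data.frame(trial_index = seq_len(nrow(post)))
  for (i in 1:7) df[[paste0("p_pi", i)]] <- post[, i]
  df$entropy <- search$entropy
  df$current_policy <- search$current_policy
  df$is_transition <- as.integer(
    df$trial_index %in% search$transitions$trial_index)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export a value-transfer model trace
#'
#' TSV with the active policy, the taken action's value before update, both
#' choice probabilities and the reward prediction error per trial.
#'
#' @param transfer a [run_value_transfer()] result.
#' @param path output file.
#' @return the exported data frame, invisibly.
#' @export
export_model_trace <- function(transfer, path) {
  n <- length(transfer$p_go)
  df <- data.frame(trial_index = seq_len(n),
                   active_policy = transfer$schedule,
                   q_chosen = transfer$q_chosen,
                   p_go = transfer$p_go,
                   rpe = transfer$rpe)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export parametric regressor time series
#'
#' Writes the four model-derived signals used as parametric regressors in
#' downstream neuroimaging GLMs, unconvolved (haemodynamic convolution is
#' tool-specific and out of scope): the taken action's value and the
#' posterior entropy at stimulus onset, the policy-transition indicator at
#' stimulus onset, and the reward prediction error at feedback onset for go
#' trials only. One row per onset event (`onset_type` stimulus or feedback).
#'
#' @param trials session data frame.
#' @param transfer a [run_value_transfer()] result (value and RPE signals).
#' @param search a [run_policy_search()] result (entropy and transitions).
#' @param path output file.
#' @return the exported data frame, invisibly.
#' @export
export_regressors <- function(trials, transfer, search, path) {
  n <- nrow(trials)
  if (length(transfer$p_go) != n || length(search$entropy) != n) {
    stop("model traces do not align with the session's trial count")
  }
  is_trans <- as.integer(seq_len(n) %in% search$transitions$trial_index)
  stim <- data.frame(trial_index = seq_len(n), onset_type = "stimulus",
                     value = transfer$q_chosen, rpe = NA_real_,
                     entropy = search$entropy, transition = is_trans,
                     stringsAsFactors = FALSE)
  go <- which(trials$action == "go")
  fb <- data.frame(trial_index = go, onset_type = "feedback",
                   value = NA_real_, rpe = transfer$rpe[go],
                   entropy = NA_real_, transition = NA_integer_,
                   stringsAsFactors = FALSE)
  df <- rbind(stim, fb)
  df <- df[order(df$trial_index, df$onset_type != "stimulus"), ]
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
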