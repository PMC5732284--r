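# The seven candidate policies: every non-empty subset of the three feature
# dimensions, in the canonical ordering used throughout (1-3 the single
# features, 4-6 the pairs, 7 all three).
POLICY_FEATURES <- list(
  `1` = "shape",
  `2` = "colour",
  `3` = "pattern",
  `4` = c("shape", "colour"),
  `5` = c("shape", "pattern"),
  `6` = c("colour", "pattern"),
  `7` = c("shape", "colour", "pattern")
)

#' Enumerate the seven feature-combination policies
#'
#' A policy is a feature subset that defines the state-space an agent
#' distinguishes stimuli in: policies 1-3 use one feature (2 states), 4-6 use
#' two (4 states), 7 uses all three (8 states).
#'
#' @return list of 7 `policy` objects with fields `id`, `features`,
#'   `dimensionality`, `n_states`.
#' @export
enumerate_policies <- function() {
  lapply(1:7, get_policy)
}

#' @rdname enumerate_policies
#' @param id policy id in 1..7.
#' @export
get_policy <- function(id) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 7L) {
    stop("policy id must be a single integer in 1..7")
  }
  feats <- POLICY_FEATURES[[id]]
  structure(list(id = id, features = feats,
                 dimensionality = length(feats),
                 n_states = 2L^length(feats)),
            class = "policy")
}

#' Dimensionality of each policy id
#' @return integer vector of length 7.
#' @export
policy_dimensionality <- function() {
  vapply(POLICY_FEATURES, length, integer(1), USE.NAMES = FALSE)
}

#' Project a stimulus into a policy's state-space
#'
#' Two stimuli that agree on the policy's features map to the same state.
#' States are indexed 1..2^d by the binary encoding of the policy's feature
#' levels in the fixed global order (shape, colour, pattern), the first
#' retained feature being the least significant bit.
#'
#' @param stimulus named list / one-row data frame with `shape`, `colour`,
#'   `pattern` labels (or 0/1 levels).
#' @param policy a `policy` from [get_policy()].
#' @return state index in 1..`policy$n_states`.
#' @export
project_state <- function(stimulus, policy) {
  stopifnot(inherits(policy, "policy"))
  lv <- vapply(policy$features, function(f) {
    v <- stimulus[[f]]
    if (is.character(v) || is.factor(v)) feature_level(as.character(v), f)
    else as.integer(v)
  }, integer(1))
  1L + as.integer(sum(lv * 2^(seq_along(lv) - 1)))
}

#' Project every trial of a session into a policy's state-space
#'
#' Vectorised companion of [project_state()].
#'
#' @param trials session data frame with `shape`, `colour`, `pattern` columns.
#' @param policy a `policy`.
#' @return integer vector of state indices, one per trial.
#' @export
project_states <- function(trials, policy) {
  stopifnot(inherits(policy, "policy"))
  idx <- rep(1L, nrow(trials))
  for (j in seq_along(policy$features)) {
    f <- policy$features[j]
    lv <- feature_level(trials[[f]], f)
    idx <- idx + lv * 2L^(j - 1L)
  }
  as.integer(idx)
}

# Feature levels of every state of a policy: n_states x dimensionality matrix
# with columns named by feature, rows in state-index order.
policy_state_levels <- function(policy) {
  d <- policy$dimensionality
  m <- matrix(0L, nrow = 2L^d, ncol = d,
              dimnames = list(NULL, policy$features))
  for (j in seq_len(d)) {
    m[, j] <- rep(rep(0:1, each = 2L^(j - 1L)), length.out = 2L^d)
  }
  m
}

#' States of one policy compatible with a state of another
#'
#' Returns all states of `policy_from` whose levels on the features shared
#' with `policy_to` agree with `state_to`. When the two policies share no
#' features the whole from-state set is returned (every from-state is vacuously
#' compatible), so a transfer mean degenerates to the grand mean.
#'
#' @param policy_from,policy_to `policy` objects.
#' @param state_to state index under `policy_to`.
#' @return integer vector of state indices under `policy_from`.
#' @export
state_preimage <- function(policy_from, policy_to, state_to) {
  stopifnot(inherits(policy_from, "policy"), inherits(policy_to, "policy"),
            state_to >= 1L, state_to <= policy_to$n_states)
  shared <- intersect(policy_from$features, policy_to$features)
  from_levels <- policy_state_levels(policy_from)
  if (length(shared) == 0L) return(seq_len(policy_from$n_states))
  to_levels <- policy_state_levels(policy_to)[state_to, , drop = TRUE]
  keep <- rep(TRUE, policy_from$n_states)
  for (f in shared) {
    keep <- keep & from_levels[, f] == to_levels[[f]]
  }
  which(keep)
}
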