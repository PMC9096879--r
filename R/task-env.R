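# Deterministic reward rules of the six-arm track.
#
# REST (the rest box) is encoded as the integer 0 throughout; track arms are
# 1..6. Reward decisions are a pure function of the visit sequence, so a
# replayed trajectory reproduces its reward flags exactly.

REST <- 0L

check_arm <- function(arm) {
  arm <- as.integer(arm)
  if (length(arm) != 1L || is.na(arm) || arm < 1L || arm > 6L) {
    stop("invalid arm id: arms are integers in 1..6", call. = FALSE)
  }
  arm
}

#' Exploration reward rule
#'
#' During the exploratory period a visit is rewarded if and only if it is
#' not a repeat of the immediately preceding arm. The first visit of a
#' session (previous location REST) is always rewarded.
#'
#' @param prev Previous arm (1..6) or `REST` (0) at a session start.
#' @param arm Arm being visited, in 1..6.
#' @return Logical reward flag.
#' @export
reward_exploration <- function(prev, arm) {
  arm <- check_arm(arm)
  prev <- as.integer(prev)
  arm != prev
}

#' Fresh alternation task state
#'
#' Tracks what the reward algorithm needs: the last beam-broken arm, the
#' most recently visited outer arm of the contingency, and the number of
#' center-arm visits this session. State resets at every session start
#' (last arm becomes REST, no outer arm on record).
#'
#' @param contingency A [contingency()].
#' @return An object of class `wt_task_state`.
#' @export
task_state <- function(contingency) {
  stopifnot(inherits(contingency, "wt_contingency"))
  structure(
    list(contingency = contingency, last_arm = REST, last_outer = NA_integer_,
         center_visits = 0L),
    class = "wt_task_state"
  )
}

#' One step of the spatial-alternation reward algorithm
#'
#' Center arm: rewarded iff the immediately preceding beam break was not at
#' the center arm (a session-start visit qualifies). Outer arm: rewarded iff
#' the immediately preceding arm was the center arm and the most recently
#' visited outer arm was not this arm; at a session start, before either
#' outer arm has been visited, the second condition is waived. Arms outside
#' the contingency are never rewarded but still update the last-visited arm
#' (their reward-well beams break like any other).
#'
#' @param state A `wt_task_state`.
#' @param arm Arm visited, in 1..6.
#' @return A list with elements `rewarded` (logical) and `state` (updated
#'   `wt_task_state`).
#' @export
alternation_step <- function(state, arm) {
  stopifnot(inherits(state, "wt_task_state"))
  arm <- check_arm(arm)
  cg <- state$contingency
  rewarded <- FALSE
  if (arm == cg$center) {
    rewarded <- state$last_arm != cg$center
    state$center_visits <- state$center_visits + 1L
  } else if (arm %in% cg$outer) {
    rewarded <- state$last_arm == cg$center &&
      (is.na(state$last_outer) || state$last_outer != arm)
    state$last_outer <- arm
  }
  state$last_arm <- arm
  list(rewarded = rewarded, state = state)
}

#' Classify a trial as inbound or outbound
#'
#' A trial is classified by where it starts: outbound trials start at the
#' center arm of the contingency (the correct choice is the outer arm not
#' visited most recently); inbound trials start anywhere else, including
#' non-contingency arms and the rest box (the correct choice is the center
#' arm).
#'
#' @param contingency A [contingency()].
#' @param from Arm the trial starts from (1..6), or `REST` (0) for the first
#'   trial of a session.
#' @return `"outbound"` or `"inbound"`.
#' @export
classify_trial <- function(contingency, from) {
  stopifnot(inherits(contingency, "wt_contingency"))
  from <- as.integer(from)
  if (length(from) != 1L || is.na(from) || from < 0L || from > 6L) {
    stop("invalid from-arm id", call. = FALSE)
  }
  if (from == contingency$center) "outbound" else "inbound"
}

#' Run one task session under a caller-supplied policy
#'
#' Drives a session with an arbitrary arm-choosing policy, applying the
#' exploration or alternation reward rule. The session starts from REST.
#' Exploration sessions end once `limit` rewards have been delivered (for a
#' non-repeating policy, `limit` visits). Alternation sessions end at the
#' first visit after the `limit`-th center-arm visit, whatever arm that
#' closing visit lands on.
#'
#' @param policy Function `(prev_arm)` returning the next arm in 1..6; called
#'   with `REST` (0) for the first visit. Returning the current arm is an
#'   error: revisits are disallowed in the model.
#' @param limit Positive session limit (center visits, or rewards for
#'   exploration).
#' @param contingency A [contingency()] for alternation sessions, or `NULL`
#'   for an exploration session.
#' @return A data frame with columns `trial`, `arm`, `rewarded`.
#' @export
run_session <- function(policy, limit, contingency = NULL) {
  stopifnot(is.function(policy), limit >= 1L)
  explore <- is.null(contingency)
  state <- if (!explore) task_state(contingency)
  arms <- integer(0)
  rewarded <- logical(0)
  prev <- REST
  n_rewards <- 0L
  repeat {
    arm <- check_arm(policy(prev))
    if (arm == prev) {
      stop("policy chose the current arm: revisits are not allowed",
           call. = FALSE)
    }
    if (explore) {
      r <- reward_exploration(prev, arm)
      n_rewards <- n_rewards + r
    } else {
      step <- alternation_step(state, arm)
      r <- step$rewarded
      state <- step$state
    }
    arms <- c(arms, arm)
    rewarded <- c(rewarded, r)
    prev <- arm
    done <- if (explore) {
      n_rewards >= limit
    } else {
      # limit-th center visit reached and at least one visit after it
      state$center_visits >= limit && arm != contingency$center ||
        state$center_visits > limit
    }
    if (done) break
    if (length(arms) > 10000L) stop("session did not terminate", call. = FALSE)
  }
  data.frame(trial = seq_along(arms), arm = arms, rewarded = as.integer(rewarded))
}

#' Replay a visit sequence through the alternation rules
#'
#' Recomputes reward flags for an arm-visit sequence within one session of a
#' given contingency. Useful for validating recorded trajectories: rewards
#' are a deterministic function of the visit sequence.
#'
#' @param contingency A [contingency()].
#' @param visits Integer vector of arms in 1..6.
#' @return Integer 0/1 reward vector, one flag per visit.
#' @export
replay_alternation <- function(contingency, visits) {
  state <- task_state(contingency)
  out <- integer(length(visits))
  for (i in seq_along(visits)) {
    step <- alternation_step(state, visits[i])
    out[i] <- as.integer(step$rewarded)
    state <- step$state
  }
  out
}
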