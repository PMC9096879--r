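# Working-memory actor-critic agents.
#
# The agent state is the pair (previous arm, current arm). With six track
# arms plus the rest box as a possible previous/current location there are
# 43 states: 36 arm-arm pairs (six of which, the same-arm pairs, are
# indexable but unreachable because revisits are disallowed), 6 states
# (REST, arm) for the first visit of a session, and 1 start state
# (REST, REST). R-side functions here are the single-step reference
# implementation; src/sim.cpp mirrors them for whole-schedule simulation.

N_STATES <- 43L

#' Model parameters
#'
#' All agents share three parameters: the learning rate `alpha` scales how
#' much each prediction error moves the propensities and values; the
#' temporal discount `gamma` weights future reward in the critic; the
#' forgetting rate `omega` decays every propensity and value geometrically
#' towards 0 (the no-preference point) each trial, letting the agent track
#' the nonstationary task. Fitting constrains `omega` to \[0.001, 0.015\]
#' (see [default_bounds()]); the constructor additionally admits the
#' no-forgetting limit `omega = 0` for analysis.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param gamma Temporal discount in \[0, 1).
#' @param omega Forgetting rate in \[0, 0.015\].
#' @return An object of class `wt_params`.
#' @export
model_params <- function(alpha, gamma, omega) {
  stopifnot(is.finite(alpha), is.finite(gamma), is.finite(omega))
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)", call. = FALSE)
  if (omega < 0 || omega > 0.015) {
    stop("omega must lie in [0, 0.015]", call. = FALSE)
  }
  structure(list(alpha = alpha, gamma = gamma, omega = omega),
            class = "wt_params")
}

#' @export
print.wt_params <- function(x, ...) {
  cat(sprintf("<params alpha=%.4g gamma=%.4g omega=%.4g>\n",
              x$alpha, x$gamma, x$omega))
  invisible(x)
}

#' Model variants
#'
#' The variants differ only in which components enter the total propensity
#' m(a, s) and are updated by the prediction error:
#' * `M1`: state-transition propensities b(a, s) only (pure working memory).
#' * `M2`: adds the dynamic independent arm preference b_arm(a).
#' * `M3`: adds dynamic neighbor preferences b_n1 (arms one away) and b_n2
#'   (arms two away).
#' * `M3noArm`: b(a, s) plus the neighbor preferences, without b_arm.
#'
#' No variant adds free parameters: all share (alpha, gamma, omega).
#'
#' @param name One of `"M1"`, `"M2"`, `"M3"`, `"M3noArm"`.
#' @return An object of class `wt_model_spec` with logical flags `use_arm`
#'   and `use_neighbor`.
#' @export
model_spec <- function(name = c("M3", "M1", "M2", "M3noArm")) {
  name <- match.arg(name)
  structure(
    list(name = name,
         use_arm = name %in% c("M2", "M3"),
         use_neighbor = name %in% c("M3", "M3noArm")),
    class = "wt_model_spec"
  )
}

#' Index the 43-element agent state space
#'
#' Bijective map from (previous arm, current arm) pairs onto 1..43. Pairs of
#' track arms occupy 1..36 in row-major order, (REST, arm) states occupy
#' 37..42, and the session-start state (REST, REST) is 43. Same-arm pairs
#' are indexable but never produced by play, since revisits are disallowed.
#'
#' @param prev Previous arm in 1..6 or `REST` (0).
#' @param cur Current arm in 1..6, or `REST` (0) only for the start state.
#' @return Integer state index in 1..43.
#' @export
state_index <- function(prev, cur) {
  prev <- as.integer(prev); cur <- as.integer(cur)
  if (is.na(prev) || is.na(cur) || prev < 0L || prev > 6L || cur < 0L || cur > 6L) {
    stop("invalid (prev, cur) pair", call. = FALSE)
  }
  if (cur == REST) {
    if (prev != REST) stop("current location can be REST only at session start",
                           call. = FALSE)
    return(N_STATES)
  }
  if (prev == REST) 36L + cur else (prev - 1L) * 6L + cur
}

# inverse of state_index, returning c(prev, cur)
state_unindex <- function(s) {
  s <- as.integer(s)
  stopifnot(s >= 1L, s <= N_STATES)
  if (s == N_STATES) return(c(REST, REST))
  if (s > 36L) return(c(REST, s - 36L))
  c((s - 1L) %/% 6L + 1L, (s - 1L) %% 6L + 1L)
}

#' Propensity components and value table
#'
#' Holds every learned quantity of an agent: the 6 x 43 state-transition
#' propensity matrix `b_trans` (target arm by state), the independent arm
#' preference 6-vector `b_arm`, the scalar neighbor preferences `b_n1` and
#' `b_n2`, and the critic value table `V` over the 43 states. All start at
#' 0, the symmetric no-preference prior that forgetting decays towards.
#'
#' @param b_trans 6 x 43 numeric matrix (default zeros).
#' @param b_arm Numeric 6-vector (default zeros).
#' @param b_n1,b_n2 Scalars (default 0).
#' @param V Numeric 43-vector (default zeros).
#' @return An object of class `wt_propensities`.
#' @export
propensity_set <- function(b_trans = matrix(0, 6L, N_STATES),
                           b_arm = numeric(6L), b_n1 = 0, b_n2 = 0,
                           V = numeric(N_STATES)) {
  stopifnot(is.matrix(b_trans), identical(dim(b_trans), c(6L, N_STATES)),
            length(b_arm) == 6L, length(V) == N_STATES,
            all(is.finite(b_trans)), all(is.finite(b_arm)),
            is.finite(b_n1), is.finite(b_n2), all(is.finite(V)))
  structure(list(b_trans = b_trans, b_arm = as.numeric(b_arm),
                 b_n1 = as.numeric(b_n1), b_n2 = as.numeric(b_n2),
                 V = as.numeric(V)),
            class = "wt_propensities")
}

# arms at distance d from cur, clipped at the track edges
neighbor_arms <- function(cur, d) {
  a <- c(cur - d, cur + d)
  a[a >= 1L & a <= 6L]
}

#' Total propensity m(a, s)
#'
#' Sums the components selected by the model variant: the state-transition
#' column b(., s), the independent arm preference, and the neighbor terms
#' b_n1 on arms one away and b_n2 on arms two away from the current arm
#' (applied in both directions where the track permits; at the edges only
#' the in-range side receives the bias). From the rest box no neighbor term
#' applies.
#'
#' @param spec A [model_spec()].
#' @param P A [propensity_set()].
#' @param prev,cur The state: previous and current location (arm or `REST`).
#' @return Numeric 6-vector of propensities over target arms 1..6.
#' @export
total_propensity <- function(spec, P, prev, cur) {
  s <- state_index(prev, cur)
  m <- P$b_trans[, s]
  if (spec$use_arm) m <- m + P$b_arm
  if (spec$use_neighbor && cur != REST) {
    m[neighbor_arms(cur, 1L)] <- m[neighbor_arms(cur, 1L)] + P$b_n1
    m[neighbor_arms(cur, 2L)] <- m[neighbor_arms(cur, 2L)] + P$b_n2
  }
  m
}

#' Softmax action probabilities with the current arm excluded
#'
#' Passes the total propensities through a softmax over the five arms other
#' than the current one; the probability of revisiting the current arm is
#' exactly 0 and the remaining probabilities sum to 1. From the rest box
#' (`cur = REST`) all six arms compete. The maximum propensity is subtracted
#' before exponentiation, so the result is invariant to adding a constant.
#'
#' @param m Numeric 6-vector of propensities.
#' @param cur Current arm in 1..6, or `REST` (0) at a session start.
#' @return Numeric 6-vector of probabilities summing to 1.
#' @export
action_probabilities <- function(m, cur) {
  stopifnot(length(m) == 6L, all(is.finite(m)))
  cur <- as.integer(cur)
  allowed <- rep(TRUE, 6L)
  if (cur != REST) allowed[cur] <- FALSE
  e <- exp(m - max(m[allowed]))
  e[!allowed] <- 0
  e / sum(e)
}

#' Temporal-difference prediction error
#'
#' delta = r + gamma * V(s') - V(s): the discrepancy between the received
#' reward plus the discounted value of the successor state and the value of
#' the state the choice was made from.
#'
#' @param r Reward (0 or 1).
#' @param v_t Value of the current state.
#' @param v_t1 Value of the successor state.
#' @param gamma Discount in \[0, 1).
#' @return The scalar prediction error.
#' @export
prediction_error <- function(r, v_t, v_t1, gamma) {
  stopifnot(gamma >= 0, gamma < 1)
  r + gamma * v_t1 - v_t
}

#' Apply one trial's learning and forgetting updates
#'
#' Implements the REINFORCE actor updates and the critic update for a
#' single trial in which the agent, in state s (indexed from `prev`, `cur`),
#' used policy `probs` and chose `chosen`, yielding prediction error
#' `delta`. Every component first decays by (1 - omega); then:
#' * b(a, s) for the visited state gains `alpha * delta * (1{a = chosen} -
#'   p(a; s))`; other states only decay. The increments across arms sum to
#'   zero because the probabilities do.
#' * b_arm(a) (if the variant uses it) gains the same form over all arms.
#' * b_n1 and b_n2 (if used) gain `alpha * delta * (1{chosen at distance i}
#'   - P_i)` where `P_i` is the summed probability mass on the arms at
#'   distance i from the current arm (one arm at the track edges).
#' * V(s) gains `alpha * delta`; other states only decay.
#'
#' A single (alpha, omega) pair governs all rules.
#'
#' @param spec A [model_spec()].
#' @param P A [propensity_set()].
#' @param prev,cur State the choice was made from (arm ids or `REST`).
#' @param chosen Arm chosen (1..6).
#' @param probs The action probabilities actually used for the choice.
#' @param delta Prediction error for the trial.
#' @param params A [model_params()] (or list with `alpha`, `omega`).
#' @return The updated `wt_propensities`.
#' @export
apply_updates <- function(spec, P, prev, cur, chosen, probs, delta, params) {
  s <- state_index(prev, cur)
  chosen <- check_arm(chosen)
  a <- params$alpha; w <- params$omega
  ind <- as.numeric(seq_len(6L) == chosen)

  P$b_trans <- P$b_trans * (1 - w)
  P$b_trans[, s] <- P$b_trans[, s] + a * delta * (ind - probs)

  if (spec$use_arm) {
    P$b_arm <- P$b_arm * (1 - w) + a * delta * (ind - probs)
  }
  if (spec$use_neighbor) {
    for (d in 1:2) {
      slot <- if (d == 1L) "b_n1" else "b_n2"
      eligible <- if (cur == REST) integer(0) else neighbor_arms(cur, d)
      p_mass <- sum(probs[eligible])
      inc <- a * delta * (as.numeric(chosen %in% eligible) - p_mass)
      P[[slot]] <- P[[slot]] * (1 - w) + inc
    }
  }
  P$V <- P$V * (1 - w)
  P$V[s] <- P$V[s] + a * delta
  P
}
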