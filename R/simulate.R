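# Whole-schedule simulation wrappers around the compiled core.

# convert a wt_schedule (plus optional forced exploration) into the list
# structure the C++ core consumes
phases_for_cpp <- function(sched, forced_explore = NULL,
                           forced_explore_sessions = NULL) {
  lapply(seq_along(sched$phases), function(i) {
    p <- sched$phases[[i]]
    forced <- integer(0)
    forced_sess <- integer(0)
    if (i == 1L && p$kind == "explore" && !is.null(forced_explore)) {
      forced <- as.integer(forced_explore)
      forced_sess <- if (is.null(forced_explore_sessions)) {
        rep(1L, length(forced))
      } else {
        as.integer(forced_explore_sessions)
      }
      stopifnot(length(forced_sess) == length(forced))
    }
    list(kind = if (p$kind == "explore") 0L else 1L,
         arms = if (is.null(p$contingency)) integer(0) else p$contingency$arms,
         n_sessions = p$n_sessions, limit = p$limit,
         cont_index = p$contingency_index,
         forced = forced, forced_sess = forced_sess)
  })
}

sim_to_trajectory <- function(sim, sched, rat_id = "agent") {
  n <- length(sim$arm)
  if (n == 0L) {
    return(data.frame(rat_id = character(0), phase = character(0),
                      contingency_label = character(0), session = integer(0),
                      trial = integer(0), arm = integer(0),
                      rewarded = integer(0)))
  }
  kind <- vapply(sched$phases, function(p) p$kind, character(1))
  labels <- vapply(sched$phases, function(p) {
    if (p$kind == "explore") "" else p$contingency$label
  }, character(1))
  phase_kind <- ifelse(kind[sim$phase] == "explore", "explore", "alt")
  # global session numbering: sessions count up across phase blocks
  nph <- max(sim$phase)
  max_sess <- vapply(seq_len(nph), function(i) {
    v <- sim$session[sim$phase == i]
    if (length(v)) max(v) else 0L
  }, integer(1))
  sess <- sim$session + cumsum(c(0L, max_sess))[sim$phase]
  grp <- paste(sim$phase, sim$session)
  trial <- stats::ave(seq_len(n), grp, FUN = seq_along)
  data.frame(rat_id = rat_id, phase = phase_kind,
             contingency_label = labels[sim$phase], session = sess,
             trial = as.integer(trial), arm = sim$arm,
             rewarded = sim$rewarded,
             contingency = sim$cont,
             stringsAsFactors = FALSE)
}

run_one_episode <- function(spec, params, sched, init = NULL,
                            forced_explore = NULL,
                            forced_explore_sessions = NULL) {
  if (is.null(init)) init <- propensity_set()
  phases <- phases_for_cpp(sched, forced_explore, forced_explore_sessions)
  sim <- sim_agent_cpp(phases, spec$use_arm, spec$use_neighbor,
                       params$alpha, params$gamma, params$omega,
                       init$b_trans, init$b_arm, init$b_n1, init$b_n2,
                       init$V)
  list(sim = sim,
       propensities = propensity_set(sim$b_trans, sim$b_arm,
                                     sim$b_n1, sim$b_n2, sim$V))
}

#' Simulate repeated episodes of an agent over a schedule
#'
#' Runs `n_repeats` independent seeded episodes of the given model variant
#' over the full schedule. Repeat `k` uses seed `seed + k`, so any prefix of
#' the repeat set is reproducible and averages over repeats are
#' deterministic for a given base seed.
#'
#' @param spec A [model_spec()].
#' @param params A [model_params()].
#' @param sched A [schedule()].
#' @param n_repeats Number of independent episodes (200 matches the
#'   model-averaging convention of the analyses).
#' @param seed Integer base seed.
#' @param init Optional starting [propensity_set()] shared by all repeats.
#' @param forced_explore Optional integer arm sequence that overrides the
#'   agent's choices during the first (exploration) phase, with
#'   `forced_explore_sessions` giving each visit's session number.
#' @param keep_propensities If `TRUE`, also return each repeat's final
#'   propensities.
#' @return A list with `trajectories` (list of trajectory data frames, one
#'   per repeat) and, optionally, `propensities`.
#' @export
run_agent <- function(spec, params, sched, n_repeats = 200L, seed = 1L,
                      init = NULL, forced_explore = NULL,
                      forced_explore_sessions = NULL,
                      keep_propensities = FALSE) {
  stopifnot(inherits(spec, "wt_model_spec"), inherits(sched, "wt_schedule"))
  if (!is.null(forced_explore)) {
    validate_forced(forced_explore, forced_explore_sessions)
  }
  trajectories <- vector("list", n_repeats)
  props <- if (keep_propensities) vector("list", n_repeats)
  for (k in seq_len(n_repeats)) {
    set.seed(seed + k)
    ep <- run_one_episode(spec, params, sched, init,
                          forced_explore, forced_explore_sessions)
    trajectories[[k]] <- sim_to_trajectory(ep$sim, sched,
                                           rat_id = paste0("rep", k))
    if (keep_propensities) props[[k]] <- ep$propensities
  }
  out <- list(trajectories = trajectories)
  if (keep_propensities) out$propensities <- props
  out
}

# fast path used by the fitting objective: raw C++ outputs, no data frames
run_raw_episodes <- function(spec, params, phases, n_repeats, seed) {
  bt0 <- matrix(0, 6L, N_STATES)
  lapply(seq_len(n_repeats), function(k) {
    set.seed(seed + k)
    sim_agent_cpp(phases, spec$use_arm, spec$use_neighbor,
                  params$alpha, params$gamma, params$omega,
                  bt0, numeric(6L), 0, 0, numeric(N_STATES))
  })
}

# per-visit trial-start arm for a raw sim, with session starts set to REST
raw_from_arms <- function(sim) {
  n <- length(sim$arm)
  from <- c(REST, sim$arm[-n])
  newsess <- c(TRUE, sim$phase[-1L] != sim$phase[-n] |
                 sim$session[-1L] != sim$session[-n])
  from[newsess] <- REST
  from
}

validate_forced <- function(visits, sessions = NULL) {
  visits <- as.integer(visits)
  if (any(visits < 1L | visits > 6L)) {
    stop("forced visits must be arms in 1..6", call. = FALSE)
  }
  if (is.null(sessions)) sessions <- rep(1L, length(visits))
  rep_ok <- c(TRUE, visits[-1L] != visits[-length(visits)] |
                sessions[-1L] != sessions[-length(sessions)])
  if (!all(rep_ok)) {
    stop("forced trajectory repeats an arm within a session, which the ",
         "model disallows", call. = FALSE)
  }
  invisible(TRUE)
}

#' Drive an agent along an observed visit sequence
#'
#' Overrides the agent's choices with an observed exploration trajectory
#' while rewards, prediction errors and every learning/forgetting update
#' proceed exactly as in free play. This is how an animal's exploratory
#' period sets the model's initial propensities before the alternation
#' phases.
#'
#' @param spec A [model_spec()].
#' @param P Starting [propensity_set()].
#' @param params A [model_params()].
#' @param visits Integer arm sequence (1..6); no within-session repeats.
#' @param sessions Optional session number per visit (default: one session).
#' @return The updated `wt_propensities` after the forced run.
#' @export
force_trajectory <- function(spec, P, params, visits, sessions = NULL) {
  stopifnot(inherits(P, "wt_propensities"))
  if (length(visits) == 0L) return(P)
  validate_forced(visits, sessions)
  if (is.null(sessions)) sessions <- rep(1L, length(visits))
  sched <- schedule(list(wt_phase("explore", NULL,
                                  n_sessions = max(sessions),
                                  limit = length(visits))))
  ep <- run_one_episode(spec, params, sched, init = P,
                        forced_explore = visits,
                        forced_explore_sessions = sessions)
  ep$propensities
}

#' Mean reward obtained on alternation phases of simulated episodes
#'
#' @param trajectories List of trajectory data frames from [run_agent()].
#' @return Mean of the reward flags over all alternation-phase visits,
#'   pooled across repeats.
#' @export
mean_alternation_reward <- function(trajectories) {
  vals <- unlist(lapply(trajectories, function(tr) {
    tr$rewarded[tr$phase == "alt"]
  }))
  mean(vals)
}
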