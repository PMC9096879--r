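# Descriptive statistics computed from arm-visit trajectories.
#
# All transition-based metrics treat the first visit of each session as
# having no predecessor: transitions and direction labels never bridge a
# session boundary.

# split visits into within-session runs; accepts a trajectory data frame
# (columns arm, session) or a bare arm vector (one session)
visit_runs <- function(traj) {
  if (is.data.frame(traj)) {
    stopifnot(all(c("arm", "session") %in% names(traj)))
    unname(split(as.integer(traj$arm), factor(traj$session,
                                              levels = unique(traj$session))))
  } else {
    list(as.integer(traj))
  }
}

#' Exploratory spatial-preference statistics
#'
#' Summarizes an exploration trajectory by its arm-visit distribution and
#' transition structure:
#' * `arm_probs`: visit probability of each of the six arms;
#' * `max_arm_prob`: the largest of these (the statistic used to test for
#'   arm preferences);
#' * `transition_matrix`: 6 x 6 row-stochastic matrix of observed
#'   transitions (rows with no outgoing transition are `NA`);
#' * `neighbor_freq`: fraction of transitions to an adjacent arm;
#' * `inertia`: fraction of consecutive transition pairs that continue in
#'   the same direction along the track;
#' * `two_away_given_not_neighbor`: among non-adjacent transitions, the
#'   fraction that go exactly two arms away.
#'
#' @param traj Trajectory data frame (columns `arm`, `session`) or integer
#'   arm vector; at least two visits.
#' @return An object of class `wt_preference_stats`.
#' @export
preference_stats <- function(traj) {
  runs <- visit_runs(traj)
  visits <- unlist(runs)
  if (length(visits) < 2L) stop("need at least two visits", call. = FALSE)
  arm_probs <- tabulate(visits, nbins = 6L) / length(visits)

  steps <- unlist(lapply(runs, function(v) if (length(v) > 1L) diff(v)))
  from <- unlist(lapply(runs, function(v) if (length(v) > 1L) v[-length(v)]))
  to <- from + steps
  tm <- matrix(0, 6L, 6L, dimnames = list(from = 1:6, to = 1:6))
  for (i in seq_along(from)) tm[from[i], to[i]] <- tm[from[i], to[i]] + 1
  rs <- rowSums(tm)
  tm <- tm / ifelse(rs > 0, rs, NA_real_)

  pairs <- unlist(lapply(runs, function(v) {
    if (length(v) > 2L) sign(diff(v)[-1L]) == sign(diff(v)[-(length(v) - 1L)])
  }))
  not_nb <- abs(steps) != 1L
  structure(
    list(arm_probs = arm_probs,
         max_arm_prob = max(arm_probs),
         transition_matrix = tm,
         neighbor_freq = mean(abs(steps) == 1L),
         inertia = if (length(pairs)) mean(pairs) else NA_real_,
         two_away_given_not_neighbor =
           if (any(not_nb)) mean(abs(steps[not_nb]) == 2L) else NA_real_,
         n_visits = length(visits), n_transitions = length(steps)),
    class = "wt_preference_stats"
  )
}

#' @export
print.wt_preference_stats <- function(x, ...) {
  cat(sprintf(paste0("<preference stats: %d visits, max arm prob %.3f, ",
                     "neighbor freq %.3f, inertia %.3f>\n"),
              x$n_visits, x$max_arm_prob, x$neighbor_freq, x$inertia))
  invisible(x)
}

# decompose one session's visits into maximal monotone runs.
# Returns a data frame with one row per run: span (arms covered) and
# n_owned (visits the run owns: its interior and terminal visit; the pivot
# visit at a direction change belongs to the run it terminates, and the
# session's first visit belongs to the first run).
sweep_runs <- function(v) {
  n <- length(v)
  if (n < 2L) return(data.frame(span = integer(0), n_owned = integer(0)))
  d <- sign(diff(v))
  brk <- which(d[-1L] != d[-length(d)])     # last transition index of a run
  starts <- c(1L, brk + 1L)                 # first transition of each run
  ends <- c(brk, length(d))                 # last transition of each run
  span <- abs(v[ends + 1L] - v[starts]) + 1L
  n_owned <- ends - starts + 1L             # one owned visit per transition
  n_owned[1L] <- n_owned[1L] + 1L           # first visit joins the first run
  data.frame(span = span, n_owned = n_owned)
}

#' Large-sweep rate
#'
#' A sweep is a maximal monotone run of consecutive arm visits; its span is
#' the number of arms it covers. Visits belonging to runs whose span
#' exceeds `span_threshold` are counted; the rate is that count over the
#' total number of visits. At a direction change, the pivot visit belongs
#' to the run it terminates. Runs never cross session boundaries.
#'
#' @param traj Trajectory data frame (columns `arm`, `session`) or integer
#'   arm vector; at least two visits.
#' @param span_threshold Sweeps spanning more than this many arms are
#'   "large" (default 3).
#' @return Fraction of visits in large sweeps.
#' @export
large_sweep_rate <- function(traj, span_threshold = 3L) {
  runs <- visit_runs(traj)
  total <- length(unlist(runs))
  if (total < 2L) stop("need at least two visits", call. = FALSE)
  counted <- sum(unlist(lapply(runs, function(v) {
    r <- sweep_runs(v)
    sum(r$n_owned[r$span > span_threshold])
  })))
  counted / total
}

#' Direction-alternation rate
#'
#' Each trial after the second of a session is labelled "continue" or
#' "reverse" according to whether the move continued in the same direction
#' along the track as the previous move. A trial is a direction alternation
#' when its label differs from the preceding trial's label (the higher-order
#' structure every alternation contingency demands). Returns the per-trial
#' binary series, an optionally smoothed series, and the mean rate.
#'
#' @param traj Trajectory data frame (columns `arm`, `session`) or integer
#'   arm vector; needs at least three transitions in some session.
#' @param smooth_sd Gaussian smoothing SD in trials (default 10); 0 for raw.
#' @return A list with `events` (0/1 vector over defined trials),
#'   `smoothed`, and `rate` (the mean).
#' @export
direction_alternation_rate <- function(traj, smooth_sd = 10) {
  runs <- visit_runs(traj)
  events <- unlist(lapply(runs, function(v) {
    if (length(v) < 4L) return(NULL)
    lab <- sign(diff(v)[-1L]) == sign(diff(v)[-(length(v) - 1L)])
    as.integer(lab[-1L] != lab[-length(lab)])
  }))
  if (is.null(events) || length(events) == 0L) {
    stop("need at least three transitions to define direction alternation",
         call. = FALSE)
  }
  list(events = events, smoothed = gaussian_smooth(events, smooth_sd),
       rate = mean(events))
}

#' Recover a contingency from its label
#'
#' @param label String such as `"234"`.
#' @return A [contingency()].
#' @export
contingency_from_label <- function(label) {
  contingency(as.integer(strsplit(as.character(label), "")[[1L]]))
}

#' Ensure a trajectory carries a contingency index column
#'
#' Contingency labels can repeat within a schedule (234 is typically run
#' twice), so analyses key on a `contingency` index: consecutive
#' alternation blocks sharing a label form one contingency, numbered in
#' order of appearance. Simulated trajectories already carry the column;
#' this reconstructs it for trajectories read from file.
#'
#' @param traj Trajectory data frame.
#' @return The trajectory with an integer `contingency` column (`NA` on
#'   exploration rows).
#' @export
ensure_contingency_index <- function(traj) {
  if (!is.null(traj[["contingency"]]) &&
      !all(is.na(traj[["contingency"]]))) return(traj)
  idx <- rep(NA_integer_, nrow(traj))
  rat <- if (is.null(traj[["rat_id"]])) rep("", nrow(traj)) else traj$rat_id
  for (rid in unique(rat)) {
    rows <- which(rat == rid & traj$phase == "alt")
    if (length(rows)) {
      r <- rle(as.character(traj$contingency_label[rows]))
      idx[rows] <- rep(seq_along(r$lengths), r$lengths)
    }
  }
  traj$contingency <- idx
  traj
}

# per-visit trial-type labels and error indicators for one contingency's
# rows of a trajectory (errors are unrewarded visits of the given type)
trial_type_errors <- function(traj, contingency) {
  stopifnot(is.data.frame(traj), inherits(contingency, "wt_contingency"))
  runs <- split(traj, factor(traj$session, levels = unique(traj$session)))
  from <- unlist(lapply(runs, function(tr) c(REST, tr$arm[-nrow(tr)])))
  type <- ifelse(from == contingency$center, "outbound", "inbound")
  list(type = type, error = 1L - traj$rewarded)
}

#' Learning curves for one contingency
#'
#' Computes, for the rows of a trajectory belonging to one contingency:
#' the per-visit reward-probability curve smoothed with a Gaussian kernel
#' (SD `smooth_sd` arm visits, confined within the contingency); the
#' inbound and outbound error-likelihood curves, smoothed in trial-type
#' index (SD `error_sd`) and linearly interpolated back onto the visit
#' index; and the trials-to-criterion statistic `trials_to_75`, the first
#' visit at which the smoothed reward probability exceeds 0.75 (`NA` if
#' never).
#'
#' @param traj Trajectory data frame for a single rat containing the
#'   contingency's visits (columns `contingency_label`, `session`, `arm`,
#'   `rewarded`).
#' @param cont_index Contingency index (position in the schedule; see
#'   [ensure_contingency_index()]).
#' @param smooth_sd SD of the reward-curve kernel in arm visits (default 10).
#' @param error_sd SD of the error-curve kernel in trials of the given type
#'   (default 2.25, the convention used when fitting models to error
#'   curves).
#' @return An object of class `wt_performance_curves`: `reward_prob`,
#'   `inbound_err`, `outbound_err` (per-visit series), `trials_to_75`, and
#'   the raw per-type error series `inbound_raw`, `outbound_raw`.
#' @export
performance_curves <- function(traj, cont_index, smooth_sd = 10,
                               error_sd = 2.25) {
  traj <- ensure_contingency_index(traj)
  rows <- traj[!is.na(traj$contingency) & traj$contingency == cont_index, ,
               drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("contingency index ", cont_index, " absent from trajectory",
         call. = FALSE)
  }
  contingency <- contingency_from_label(rows$contingency_label[1L])
  reward_prob <- gaussian_smooth(rows$rewarded, smooth_sd)
  tt <- trial_type_errors(rows, contingency)
  n <- nrow(rows)
  out <- list(reward_prob = reward_prob,
              trials_to_75 = first_crossing(reward_prob, 0.75, censor = FALSE))
  for (ty in c("inbound", "outbound")) {
    sel <- which(tt$type == ty)
    raw <- tt$error[sel]
    sm <- gaussian_smooth(raw, error_sd)
    # interpolate from trial-type index back to visit index
    curve <- if (length(sel) >= 2L) {
      stats::approx(sel, sm, xout = seq_len(n), rule = 2)$y
    } else if (length(sel) == 1L) {
      rep(sm, n)
    } else {
      rep(NA_real_, n)
    }
    out[[paste0(ty, "_err")]] <- curve
    out[[paste0(ty, "_raw")]] <- raw
  }
  structure(out, class = "wt_performance_curves")
}

#' Per-contingency reward rates
#'
#' @param traj Trajectory data frame for one rat.
#' @return Numeric vector of mean reward per visit for each alternation
#'   contingency index, named by contingency label.
#' @export
reward_rates <- function(traj) {
  traj <- ensure_contingency_index(traj)
  alt <- traj[!is.na(traj$contingency), , drop = FALSE]
  idx <- sort(unique(alt$contingency))
  out <- vapply(idx, function(i) mean(alt$rewarded[alt$contingency == i]),
                numeric(1))
  names(out) <- vapply(idx, function(i) {
    as.character(alt$contingency_label[alt$contingency == i][1L])
  }, character(1))
  out
}
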