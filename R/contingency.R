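#' Alternation contingency
#'
#' A contingency is an ordered triple of track arms (outer-low, center,
#' outer-high) that can deliver reward under the spatial-alternation rule.
#' The remaining three arms of the six-arm track are never rewarded while
#' the contingency is active.
#'
#' @param arms Integer vector of length 3 with distinct arm ids in 1..6.
#'   The middle element is the center arm.
#' @return An object of class `wt_contingency` with elements `arms`,
#'   `center`, `outer` and `label` (e.g. `"234"`).
#' @examples
#' contingency(c(2, 3, 4))
#' @export
contingency <- function(arms) {
  arms <- as.integer(arms)
  if (length(arms) != 3L || anyNA(arms) || any(arms < 1L | arms > 6L) ||
      anyDuplicated(arms)) {
    stop("a contingency needs three distinct arms in 1..6", call. = FALSE)
  }
  structure(
    list(arms = arms, center = arms[2L], outer = arms[c(1L, 3L)],
         label = paste(arms, collapse = "")),
    class = "wt_contingency"
  )
}

#' @export
print.wt_contingency <- function(x, ...) {
  cat("<contingency ", x$label, ": center arm ", x$center, ">\n", sep = "")
  invisible(x)
}

#' The canonical sequence of six alternation contingencies
#'
#' The default ordering presents an easy transition first (234 to 123),
#' then a harder one (123 to 345, whose center arm is new), the hardest
#' contingency (246, which requires skipping arms), and two comparison
#' contingencies (234 again, then 456).
#'
#' @return A list of six [contingency()] objects: 234, 123, 345, 246, 234, 456.
#' @export
default_contingencies <- function() {
  lapply(list(c(2, 3, 4), c(1, 2, 3), c(3, 4, 5),
              c(2, 4, 6), c(2, 3, 4), c(4, 5, 6)), contingency)
}

wt_phase <- function(kind, contingency = NULL, n_sessions, limit,
                     contingency_index = NA_integer_) {
  stopifnot(kind %in% c("explore", "alt"), n_sessions >= 1L, limit >= 1L)
  if (kind == "alt" && is.null(contingency)) {
    stop("alternation phases need a contingency", call. = FALSE)
  }
  list(kind = kind, contingency = contingency,
       n_sessions = as.integer(n_sessions), limit = as.integer(limit),
       contingency_index = as.integer(contingency_index))
}

#' Build a task schedule
#'
#' A schedule is an ordered list of phase blocks. Each block is either an
#' exploration block (sessions end after `limit` rewards; with no immediate
#' revisits every visit is rewarded, so `limit` equals the visit count) or an
#' alternation block on a given contingency (sessions end after `limit`
#' center-arm visits plus one further visit).
#'
#' @param phases A list of phase blocks as built internally; most users
#'   should call [default_schedule()] instead.
#' @return An object of class `wt_schedule`.
#' @seealso [default_schedule()]
#' @export
schedule <- function(phases) {
  stopifnot(is.list(phases), length(phases) > 0L)
  structure(list(phases = phases), class = "wt_schedule")
}

#' Default experimental schedule
#'
#' Mirrors the automated-experiment design: roughly two weeks of track
#' exploration followed by six alternation contingencies run three sessions
#' per day. Session lengths ramp up at the start of each contingency: the
#' very first alternation day uses 10 center visits per session, the first
#' day of every later contingency (and day two of the first) uses 20, and
#' all remaining days use 40.
#'
#' @param contingencies List of [contingency()] objects, in presentation
#'   order. Default [default_contingencies()].
#' @param explore_sessions Number of exploration sessions (default 15).
#' @param explore_rewards Rewards (= visits, for a non-repeating agent) per
#'   exploration session (default 26, giving 390 exploration trials,
#'   inside the observed 362-425 range).
#' @param days_per_contingency Integer vector (recycled) of days each
#'   contingency is run (default 3).
#' @param sessions_per_day Sessions per day (default 3).
#' @return A `wt_schedule`.
#' @export
default_schedule <- function(contingencies = default_contingencies(),
                             explore_sessions = 15L,
                             explore_rewards = 26L,
                             days_per_contingency = 3L,
                             sessions_per_day = 3L) {
  days <- rep_len(as.integer(days_per_contingency), length(contingencies))
  phases <- list()
  if (explore_sessions > 0L) {
    phases[[1L]] <- wt_phase("explore", NULL, explore_sessions, explore_rewards)
  }
  for (i in seq_along(contingencies)) {
    for (d in seq_len(days[i])) {
      limit <- if (i == 1L && d == 1L) 10L else if (d == 1L || (i == 1L && d == 2L)) 20L else 40L
      phases[[length(phases) + 1L]] <-
        wt_phase("alt", contingencies[[i]], sessions_per_day, limit,
                 contingency_index = i)
    }
  }
  schedule(phases)
}

#' @export
print.wt_schedule <- function(x, ...) {
  cat("<schedule with", length(x$phases), "phase blocks>\n")
  for (p in x$phases) {
    lab <- if (p$kind == "explore") "explore" else p$contingency$label
    cat(sprintf("  %-8s sessions=%d limit=%d\n", lab, p$n_sessions, p$limit))
  }
  invisible(x)
}

#' Read or write a schedule as YAML
#'
#' The YAML form is a list of blocks with fields `kind`, `arms` (absent for
#' exploration), `sessions` and `limit`.
#'
#' @param path File path.
#' @param sched A `wt_schedule` (for writing).
#' @return `read_schedule` returns a `wt_schedule`; `write_schedule` returns
#'   `path` invisibly.
#' @export
read_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  idx <- 0L
  last_label <- ""
  phases <- lapply(raw, function(b) {
    if (identical(b$kind, "explore")) {
      wt_phase("explore", NULL, b$sessions, b$limit)
    } else {
      cg <- contingency(b$arms)
      if (!identical(cg$label, last_label)) idx <<- idx + 1L
      last_label <<- cg$label
      wt_phase("alt", cg, b$sessions, b$limit, contingency_index = idx)
    }
  })
  schedule(phases)
}

#' @rdname read_schedule
#' @export
write_schedule <- function(sched, path) {
  stopifnot(inherits(sched, "wt_schedule"))
  blocks <- lapply(sched$phases, function(p) {
    if (p$kind == "explore") {
      list(kind = "explore", sessions = p$n_sessions, limit = p$limit)
    } else {
      list(kind = "alt", arms = p$contingency$arms,
           sessions = p$n_sessions, limit = p$limit)
    }
  })
  yaml::write_yaml(blocks, path)
  invisible(path)
}

# number of distinct contingency blocks in a schedule
n_contingencies <- function(sched) {
  idx <- vapply(sched$phases, function(p) p$contingency_index, integer(1))
  if (all(is.na(idx))) 0L else max(idx, na.rm = TRUE)
}

# restrict a schedule to phases up to and including contingency `k`
truncate_schedule <- function(sched, k) {
  keep <- vapply(sched$phases, function(p) {
    is.na(p$contingency_index) || p$contingency_index <= k
  }, logical(1))
  schedule(sched$phases[keep])
}
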