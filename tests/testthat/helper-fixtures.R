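# Shared fixtures: small schedules and deterministic policies.

# perfect-alternation policy for a contingency; `start_outer` controls
# whether the first visit of the session is an outer arm or the center
perfect_policy <- function(cg, start_outer = FALSE) {
  last_outer <- NULL
  first <- TRUE
  function(prev) {
    if (first) {
      first <<- FALSE
      if (start_outer) {
        last_outer <<- cg$outer[2L]
        return(cg$outer[2L])
      }
      return(cg$center)
    }
    if (prev == cg$center) {
      nxt <- if (is.null(last_outer)) cg$outer[2L] else setdiff(cg$outer, last_outer)
      last_outer <<- nxt
      nxt
    } else {
      cg$center
    }
  }
}

# hand enumeration of the perfect rewarded sequence used as an oracle:
# generates the first n visits of perfect alternation for a contingency
perfect_sequence <- function(cg, n, start_outer = FALSE) {
  pol <- perfect_policy(cg, start_outer)
  v <- integer(n)
  prev <- 0L
  for (i in seq_len(n)) {
    v[i] <- pol(prev)
    prev <- v[i]
  }
  v
}

# small schedule for fast end-to-end tests: short exploration plus the
# first `n_cont` contingencies, one day each
tiny_schedule <- function(n_cont = 3L, explore_sessions = 4L,
                          explore_rewards = 15L) {
  default_schedule(contingencies = default_contingencies()[seq_len(n_cont)],
                   explore_sessions = explore_sessions,
                   explore_rewards = explore_rewards,
                   days_per_contingency = 1L)
}

# random propensity set for property checks
random_propensities <- function(seed = 1L, scale = 1) {
  set.seed(seed)
  propensity_set(b_trans = matrix(rnorm(6 * 43, sd = scale), 6, 43),
                 b_arm = rnorm(6, sd = scale),
                 b_n1 = rnorm(1, sd = scale), b_n2 = rnorm(1, sd = scale),
                 V = rnorm(43, sd = scale))
}
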