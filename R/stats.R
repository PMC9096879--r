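# Monte-Carlo and permutation inference for exploratory preferences and
# model comparisons.

#' Monte-Carlo p-value against a simulated null
#'
#' Draws `n_draws` realizations of a statistic under a caller-supplied null
#' sampler and returns the fraction of draws at least as large as the
#' observed value, floored at `1/n_draws` (with 10,000 draws the smallest
#' attainable p is 1e-4).
#'
#' @param observed Observed statistic.
#' @param null_sampler Zero-argument function returning one draw of the
#'   statistic under the null.
#' @param n_draws Number of null draws (default 10000).
#' @param seed Optional integer seed.
#' @return The Monte-Carlo p-value.
#' @export
mc_null_p <- function(observed, null_sampler, n_draws = 10000L, seed = NULL) {
  if (n_draws <= 0L) stop("n_draws must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(i) null_sampler(), numeric(1))
  max(mean(draws >= observed), 1 / n_draws)
}

#' Null samplers for exploratory-preference statistics
#'
#' Build the three null visit-sequence generators used to test whether a
#' rat's exploratory preferences deviate from chance:
#' * `"uniform"`: arms drawn uniformly and independently (the null for the
#'   maximum arm-visit probability);
#' * `"arm_probs"`: arms drawn independently from the rat's own empirical
#'   arm-visit probabilities (the null for the neighbor-transition
#'   frequency);
#' * `"transitions"`: a Markov chain over arms driven by the rat's own
#'   empirical transition matrix (the null for directional inertia).
#'
#' Generated sequences reproduce the rat's session structure (same number
#' of visits per session), so the statistic's sampling distribution matches
#' the data's.
#'
#' @param traj Trajectory data frame (columns `arm`, `session`) or arm
#'   vector.
#' @param mode Which null to sample.
#' @param stat Function mapping a visit data frame to the statistic, e.g.
#'   `function(tr) preference_stats(tr)$max_arm_prob`.
#' @return A zero-argument sampler suitable for [mc_null_p()].
#' @export
null_preference_sampler <- function(traj,
                                    mode = c("uniform", "arm_probs",
                                             "transitions"),
                                    stat) {
  mode <- match.arg(mode)
  runs <- visit_runs(traj)
  lens <- lengths(runs)
  ps <- preference_stats(traj)
  tm <- ps$transition_matrix
  tm[is.na(tm)] <- 1 / 6   # unvisited rows: uniform fallback
  arm_probs <- ps$arm_probs

  draw_session <- function(n) {
    switch(mode,
      uniform = sample.int(6L, n, replace = TRUE),
      arm_probs = sample.int(6L, n, replace = TRUE, prob = arm_probs),
      transitions = {
        v <- integer(n)
        v[1L] <- sample.int(6L, 1L, prob = arm_probs)
        for (i in seq_len(n - 1L)) {
          v[i + 1L] <- sample.int(6L, 1L, prob = tm[v[i], ])
        }
        v
      })
  }
  function() {
    vis <- lapply(lens, draw_session)
    df <- data.frame(arm = unlist(vis),
                     session = rep(seq_along(lens), lens))
    stat(df)
  }
}

#' Per-rat randomness evidence for one preference statistic
#'
#' For each rat, computes the Monte-Carlo probability of seeing a
#' preference statistic at least as extreme as observed under the matched
#' null — the per-animal evidence Phi that the rat is behaving randomly
#' with respect to that statistic.
#'
#' @param cohort Named list of per-rat exploration trajectories.
#' @param stat Statistic function as in [null_preference_sampler()].
#' @param mode Null mode as in [null_preference_sampler()].
#' @param n_draws Null draws per rat (default 10000).
#' @param seed Integer seed.
#' @return Named numeric vector of per-rat probabilities.
#' @export
cohort_randomness_evidence <- function(cohort, stat,
                                       mode = c("uniform", "arm_probs",
                                                "transitions"),
                                       n_draws = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  phis <- vapply(seq_along(cohort), function(i) {
    traj <- cohort[[i]]
    obs <- stat(if (is.data.frame(traj)) traj else data.frame(
      arm = traj, session = 1L))
    sampler <- null_preference_sampler(traj, mode, stat)
    mc_null_p(obs, sampler, n_draws = n_draws, seed = seed + i)
  }, numeric(1))
  names(phis) <- names(cohort)
  phis
}

#' Population-level randomness test
#'
#' Tests whether the population probability of a subject behaving randomly
#' is 0.5 against the one-tailed alternative that it is smaller. Each
#' animal carries evidence `phi[i]` = p(data | random). Each Monte-Carlo
#' sample classifies every animal independently as random with probability
#' `phi[i]`, counts the random subjects m, and evaluates the fair-binomial
#' lower tail `sum_{k<=m} choose(N, k) / 2^N`; the returned p-value is the
#' average tail over samples. With every `phi` near 0 and N animals the
#' p-value approaches `2^-N`.
#'
#' @param phi Numeric vector of per-animal randomness probabilities in
#'   \[0, 1\].
#' @param n_samples Monte-Carlo samples (default 100000).
#' @param seed Optional integer seed.
#' @param exact If `TRUE`, compute the exact mixture by Poisson-binomial
#'   convolution instead of sampling (used as an oracle for moderate N).
#' @return The population p-value.
#' @export
population_randomness_test <- function(phi, n_samples = 100000L, seed = NULL,
                                       exact = FALSE) {
  if (length(phi) == 0L) stop("empty evidence vector", call. = FALSE)
  stopifnot(all(phi >= 0 & phi <= 1))
  N <- length(phi)
  if (exact) {
    # distribution of the number of random subjects, by convolution
    pm <- 1
    for (p in phi) pm <- c(pm * (1 - p), 0) + c(0, pm * p)
    return(sum(pm * stats::pbinom(0:N, N, 0.5)))
  }
  if (!is.null(seed)) set.seed(seed)
  total <- 0
  left <- n_samples
  while (left > 0L) {                      # chunked to bound memory
    k <- min(left, 100000L)
    m <- rowSums(matrix(stats::runif(k * N), k, N) <
                   matrix(phi, k, N, byrow = TRUE))
    total <- total + sum(stats::pbinom(m, N, 0.5))
    left <- left - k
  }
  total / n_samples
}

#' Paired permutation test by sign flipping
#'
#' Tests whether paired per-animal values differ, using the mean paired
#' difference as the statistic and random sign flips of the differences as
#' the permutation distribution. P-values use add-one smoothing, so the
#' floor is `1/(n_perms + 1)`.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @param n_perms Number of sign-flip permutations (default 10000).
#' @param seed Optional integer seed.
#' @param tail `"two"`, `"greater"` (mean x > mean y) or `"less"`.
#' @return A list with `p`, `statistic` (mean difference) and `n_perms`.
#' @export
paired_permutation_test <- function(x, y, n_perms = 10000L, seed = NULL,
                                    tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- x - y
  obs <- mean(d)
  n <- length(d)
  perms <- vapply(seq_len(n_perms), function(i) {
    mean(d * sample(c(-1, 1), n, replace = TRUE))
  }, numeric(1))
  p <- switch(tail,
    two = (1 + sum(abs(perms) >= abs(obs))) / (n_perms + 1),
    greater = (1 + sum(perms >= obs)) / (n_perms + 1),
    less = (1 + sum(perms <= obs)) / (n_perms + 1))
  list(p = p, statistic = obs, n_perms = n_perms)
}

# mean-over-contingency crossing delay of a group of repeat curves against
# the animal reference; curves: list per contingency of nRep x nTrial
# matrices, animal: list of reference curves
crossing_delay <- function(curves, animal, smooth_sd, threshold) {
  delays <- vapply(seq_along(curves), function(j) {
    avg <- colMeans(curves[[j]])
    if (smooth_sd > 0) avg <- gaussian_smooth(avg, smooth_sd)
    model_cross <- first_crossing(avg, threshold, censor = TRUE)
    animal_cross <- first_crossing(animal[[j]], threshold, censor = TRUE)
    model_cross - animal_cross
  }, numeric(1))
  mean(delays)
}

#' Permutation test on the difference of 75%-crossing delays
#'
#' Compares how much later than an animal reference two model variants
#' reach criterion. For each group the statistic d is the average, over
#' contingencies, of (trial at which the group's mean curve first exceeds
#' the threshold) minus (the animal curve's crossing trial); curves that
#' never cross are censored at the final trial + 1. The observed
#' `delta = d_A - d_B` is located within the distribution obtained by
#' permuting the pooled repeat labels (a repeat keeps its curves across all
#' contingencies); the reported p is the upper-tail quantile
#' `P(delta_perm >= delta_obs)` with add-one smoothing.
#'
#' @param repeats_a,repeats_b Lists (one element per contingency) of
#'   repeat-by-trial 0/1 or probability matrices; repeat rows are aligned
#'   across contingencies within each group.
#' @param animal List of per-contingency reference curves (same trial
#'   lengths).
#' @param n_perms Number of label permutations (default 10000).
#' @param seed Optional integer seed.
#' @param smooth_sd Gaussian SD applied to group mean curves before
#'   crossing detection (default 10 trials; 0 disables). The animal
#'   reference is used as given.
#' @param threshold Crossing threshold (default 0.75).
#' @return A list with `p`, `delta` (observed d_A - d_B), `d_a`, `d_b`.
#' @export
crossing_permutation_test <- function(repeats_a, repeats_b, animal,
                                      n_perms = 10000L, seed = NULL,
                                      smooth_sd = 10, threshold = 0.75) {
  stopifnot(length(repeats_a) == length(repeats_b),
            length(animal) == length(repeats_a))
  if (!is.null(seed)) set.seed(seed)
  n_a <- nrow(repeats_a[[1L]])
  n_b <- nrow(repeats_b[[1L]])
  pooled <- lapply(seq_along(repeats_a), function(j) {
    rbind(repeats_a[[j]], repeats_b[[j]])
  })
  d_a <- crossing_delay(repeats_a, animal, smooth_sd, threshold)
  d_b <- crossing_delay(repeats_b, animal, smooth_sd, threshold)
  delta_obs <- d_a - d_b
  perms <- vapply(seq_len(n_perms), function(i) {
    idx <- sample.int(n_a + n_b)
    ia <- idx[seq_len(n_a)]
    ib <- idx[n_a + seq_len(n_b)]
    crossing_delay(lapply(pooled, function(m) m[ia, , drop = FALSE]),
                   animal, smooth_sd, threshold) -
      crossing_delay(lapply(pooled, function(m) m[ib, , drop = FALSE]),
                     animal, smooth_sd, threshold)
  }, numeric(1))
  p <- (1 + sum(perms >= delta_obs)) / (n_perms + 1)
  list(p = p, delta = delta_obs, d_a = d_a, d_b = d_b, n_perms = n_perms)
}

#' Variance in rank ordering explained
#'
#' Squared correlation between the rank orderings of two per-animal value
#' vectors (ties get average ranks). Both a perfectly preserved and a
#' perfectly reversed ordering give 1: the statistic measures how much of
#' the variance in one ordering a linear relation on the other captures.
#'
#' @param a,b Equal-length numeric vectors, length at least 3.
#' @return The rank-order r-squared in \[0, 1\].
#' @export
rank_order_r2 <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    stop("need two aligned vectors of length >= 3", call. = FALSE)
  }
  stats::cor(rank(a), rank(b))^2
}

#' Median-split comparison of outcomes
#'
#' Splits animals at the median of `scores` (strictly above the median
#' versus the rest; the split depends only on score ranks) and compares
#' `outcomes` between the halves with the Wilcoxon rank-sum test.
#'
#' @param scores Per-animal scores driving the split (all equal is an
#'   error: the split is undefined).
#' @param outcomes Per-animal outcomes to compare.
#' @return A list with `high` (logical group membership), group means
#'   `mean_high` and `mean_low`, and the rank-sum `p`.
#' @export
median_split_compare <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes), length(scores) >= 4L)
  if (length(unique(scores)) == 1L) {
    stop("all scores equal: median split undefined", call. = FALSE)
  }
  high <- scores > stats::median(scores)
  if (!any(high) || all(high)) {
    stop("median split produced an empty group", call. = FALSE)
  }
  p <- suppressWarnings(
    stats::wilcox.test(outcomes[high], outcomes[!high])$p.value)
  if (is.nan(p)) p <- 1   # fully tied outcomes carry no evidence
  list(high = high, mean_high = mean(outcomes[high]),
       mean_low = mean(outcomes[!high]), p = p)
}
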