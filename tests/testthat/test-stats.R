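# Monte-Carlo nulls, the population randomness test, permutation tests.

test_that("Monte-Carlo p-values respect their floor and symmetry", {
  set.seed(41)
  sampler <- function() rnorm(1)
  # observed below every draw
  expect_equal(mc_null_p(-100, sampler, n_draws = 500, seed = 1), 1)
  # observed above every draw: floored at 1/n_draws
  expect_equal(mc_null_p(100, sampler, n_draws = 500, seed = 1), 1 / 500)
  expect_equal(mc_null_p(100, sampler, n_draws = 10000, seed = 1), 1e-4)
  # observed at the median: about one half
  p <- mc_null_p(0, sampler, n_draws = 2000, seed = 2)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 2000))
  expect_error(mc_null_p(0, sampler, n_draws = 0), "positive")
})

test_that("preference null samplers reproduce the conditioning they claim", {
  set.seed(42)
  v <- integer(600)
  v[1] <- 2L
  for (i in 2:600) {          # biased chain: prefers arm min(prev+1, 6)
    probs <- rep(1, 6); probs[min(v[i - 1L] + 1L, 6L)] <- 8
    probs[v[i - 1L]] <- 0
    v[i] <- sample.int(6L, 1L, prob = probs)
  }
  tr <- data.frame(arm = v, session = rep(1:6, each = 100))
  obs_probs <- preference_stats(tr)$arm_probs
  # arm-probability-preserving null keeps the marginal arm distribution
  sampler <- null_preference_sampler(tr, "arm_probs",
                                     function(x) preference_stats(x)$arm_probs)
  draws <- replicate(200, sampler())
  expect_lt(max(abs(rowMeans(draws) - obs_probs)), 0.02)
  # uniform null is uniform regardless of the data
  sampler_u <- null_preference_sampler(tr, "uniform",
                                       function(x) preference_stats(x)$arm_probs)
  draws_u <- replicate(200, sampler_u())
  expect_lt(max(abs(rowMeans(draws_u) - 1 / 6)), 0.02)
  # transition-preserving null reproduces the neighbor frequency
  sampler_t <- null_preference_sampler(tr, "transitions",
                                       function(x) preference_stats(x)$neighbor_freq)
  nb <- mean(replicate(200, sampler_t()))
  expect_lt(abs(nb - preference_stats(tr)$neighbor_freq), 0.03)
})

test_that("population randomness test matches its closed-form limits", {
  # all animals certainly random
  expect_equal(population_randomness_test(rep(1, 10), exact = TRUE), 1)
  # no animal random: lower tail at m = 0 is 2^-N
  expect_equal(population_randomness_test(rep(0, 24), exact = TRUE),
               1 / 2^24)
  p <- population_randomness_test(rep(0, 24), n_samples = 1000, seed = 1)
  expect_equal(p, 1 / 2^24)
  # single ambiguous animal
  expect_equal(population_randomness_test(0, exact = TRUE), 0.5)
  expect_error(population_randomness_test(numeric(0)), "empty")
})

test_that("sampled population test agrees with exact enumeration for N <= 12", {
  set.seed(43)
  for (N in c(3L, 8L, 12L)) {
    phi <- runif(N)
    exact <- population_randomness_test(phi, exact = TRUE)
    sampled <- population_randomness_test(phi, n_samples = 400000L,
                                          seed = 100 + N)
    expect_lt(abs(sampled - exact), 1e-3)
  }
})

test_that("paired permutation test is exact on degenerate inputs", {
  x <- rnorm(20)
  expect_equal(paired_permutation_test(x, x, n_perms = 200, seed = 1)$p, 1)
  # 20 unanimous +1 differences, one-tailed: only the all-positive flip
  # pattern reaches the observed mean, so p hits the add-one floor
  res <- paired_permutation_test(rep(1, 20), rep(0, 20), n_perms = 10000,
                                 seed = 2, tail = "greater")
  expect_equal(res$p, 1 / 10001)
  # antisymmetry of the one-tailed p under swapping the groups
  set.seed(3)
  a <- rnorm(15); b <- rnorm(15) + 0.3
  p1 <- paired_permutation_test(a, b, n_perms = 4000, seed = 4,
                                tail = "greater")$p
  p2 <- paired_permutation_test(b, a, n_perms = 4000, seed = 4,
                                tail = "less")$p
  expect_equal(p1, p2)
})

test_that("paired permutation p-values are uniform under exchangeability", {
  set.seed(44)
  ps <- replicate(100, {
    x <- rnorm(20); y <- rnorm(20)
    paired_permutation_test(x, y, n_perms = 400)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("crossing permutation test separates and calibrates", {
  make_curves <- function(n_rep, n_trial, cross_at, noise_sd = 8) {
    t(vapply(seq_len(n_rep), function(i) {
      c0 <- cross_at + rnorm(1, 0, noise_sd)
      plogis((seq_len(n_trial) - c0) / 6)
    }, numeric(n_trial)))
  }
  # identical groups: observed delta is exactly zero, p near one half
  set.seed(45)
  a <- list(make_curves(20, 200, 80))
  animal <- list(plogis((1:200 - 60) / 6))
  res <- crossing_permutation_test(a, a, animal, n_perms = 400, seed = 1,
                                   smooth_sd = 0)
  expect_equal(res$delta, 0)
  expect_gt(res$p, 0.2); expect_lt(res$p, 0.8)
  # group B crossing at the animal reference, group A far later
  b <- list(make_curves(20, 200, 60))
  late <- list(make_curves(20, 200, 150))
  res2 <- crossing_permutation_test(late, b, animal, n_perms = 1000,
                                    seed = 2, smooth_sd = 0)
  expect_lt(res2$p, 0.01)
  expect_gt(res2$delta, 0)
  # never-crossing group curves are censored, not an error
  flat <- list(matrix(0.1, 10, 200))
  res3 <- crossing_permutation_test(flat, b[1], animal, n_perms = 50,
                                    seed = 3, smooth_sd = 0)
  expect_equal(res3$d_a,
               201 - wtrackrl:::first_crossing(animal[[1]], 0.75))
})

test_that("crossing permutation p-values are uniform under exchangeability", {
  set.seed(46)
  make_curves <- function(n_rep, n_trial, cross_at) {
    t(vapply(seq_len(n_rep), function(i) {
      c0 <- cross_at + rnorm(1, 0, 15)
      plogis((seq_len(n_trial) - c0) / 5)
    }, numeric(n_trial)))
  }
  animal <- list(plogis((1:150 - 50) / 5))
  ps <- replicate(100, {
    pool <- make_curves(24, 150, 70)
    idx <- sample.int(24)
    crossing_permutation_test(list(pool[idx[1:12], ]),
                              list(pool[idx[13:24], ]),
                              animal, n_perms = 200, smooth_sd = 0)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("rank-order variance explained has its closed-form extremes", {
  set.seed(47)
  a <- rnorm(24)
  expect_equal(rank_order_r2(a, a), 1)
  expect_equal(rank_order_r2(a, -a), 1)   # reversed ordering is linear too
  expect_equal(rank_order_r2(a, 2 * a + 5), 1)  # monotone transform
  # independent orderings: mean r2 is 1/(n-1)
  n <- 24
  r2s <- replicate(2000, rank_order_r2(rnorm(n), rnorm(n)))
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 0.006)
  expect_error(rank_order_r2(1:2, 1:2), "length >= 3")
})

test_that("median split compares outcomes by rank sum", {
  scores <- c(1:24)
  # identical outcomes across groups: p = 1
  res <- median_split_compare(scores, rep(1, 24))
  expect_equal(res$p, 1)
  # perfectly separated outcomes: exact two-sided tail for 12 vs 12
  res2 <- median_split_compare(scores, scores)
  expect_equal(res2$p, 2 / choose(24, 12))
  expect_equal(res2$mean_high - res2$mean_low, 12)
  # split depends only on ranks
  res3 <- median_split_compare(exp(scores / 3), scores)
  expect_identical(res3$high, res2$high)
  expect_error(median_split_compare(rep(2, 10), rnorm(10)), "undefined")
})
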