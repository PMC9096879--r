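# Agent state space, policy, prediction error and learning rules.

test_that("the state space has exactly 43 states, six of them unreachable pairs", {
  idx <- integer(0)
  for (p in 0:6) for (cu in 0:6) {
    s <- tryCatch(state_index(p, cu), error = function(e) NA_integer_)
    if (!is.na(s)) idx <- c(idx, s)
  }
  expect_identical(length(idx), 43L)
  expect_identical(sort(idx), 1:43)
  # the six same-arm pairs are indexable but never produced by play
  same <- vapply(1:6, function(a) state_index(a, a), integer(1))
  expect_identical(length(unique(same)), 6L)
  expect_identical(state_index(0, 0), 43L)
  expect_error(state_index(3, 0), "session start")
  # bijectivity: the inverse map round-trips
  for (s in 1:43) {
    pc <- wtrackrl:::state_unindex(s)
    expect_identical(state_index(pc[1], pc[2]), s)
  }
})

test_that("simulated play never enters a same-arm state", {
  sched <- tiny_schedule(2L)
  res <- run_agent(model_spec("M3"), model_params(0.5, 0.5, 0.005), sched,
                   n_repeats = 3L, seed = 7L)
  for (tr in res$trajectories) {
    for (s in split(tr$arm, paste(tr$phase, tr$session))) {
      if (length(s) > 1L) expect_true(all(diff(s) != 0L))
    }
  }
})

test_that("action probabilities normalize with zero mass on the current arm", {
  expect_equal(action_probabilities(rep(0, 6), 6),
               c(rep(0.2, 5), 0))
  # hand softmax: exp(ln 2) = 2 against four units
  expect_equal(action_probabilities(c(0, 0, log(2), 0, 0, 0), 6),
               c(1, 1, 2, 1, 1, 0) / 6)
  # property over random propensities and all current arms (REST included)
  set.seed(4)
  for (i in 1:50) {
    m <- rnorm(6, sd = 3)
    cur <- sample(0:6, 1)
    p <- action_probabilities(m, cur)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    if (cur > 0) expect_identical(p[cur], 0)
    expect_true(all(p >= 0))
  }
})

test_that("softmax is invariant to adding a constant to all propensities", {
  set.seed(5)
  for (i in 1:25) {
    m <- rnorm(6, sd = 2)
    cur <- sample(0:6, 1)
    shift <- rnorm(1, sd = 50)
    expect_equal(action_probabilities(m, cur),
                 action_probabilities(m + shift, cur), tolerance = 1e-12)
  }
  # large propensities do not overflow
  expect_equal(sum(action_probabilities(c(1000, 1000, 999, 0, 0, 0), 6)), 1)
})

test_that("prediction error follows the TD form", {
  expect_identical(prediction_error(1, 0, 0, 0.9), 1)
  expect_equal(prediction_error(0, 0.1, 0.4, 0.5), 0.1)
  # fixed point: reward matching expectation gives zero error
  gamma <- 0.7; v1 <- 0.35
  expect_equal(prediction_error(1, 1 + gamma * v1, v1, gamma), 0)
})

test_that("update increments are zero-sum per state and arm set", {
  spec <- model_spec("M3")
  params <- model_params(0.6, 0.5, 0)
  set.seed(6)
  for (i in 1:20) {
    P <- random_propensities(seed = i)
    prev <- sample(0:6, 1)
    cur <- if (prev == 0 && runif(1) < 0.3) 0L else sample(1:6, 1)
    if (cur == 0 && prev != 0) cur <- sample(1:6, 1)
    m <- total_propensity(spec, P, prev, cur)
    probs <- action_probabilities(m, cur)
    chosen <- sample(which(probs > 0), 1)
    delta <- rnorm(1)
    P2 <- apply_updates(spec, P, prev, cur, chosen, probs, delta, params)
    s <- state_index(prev, cur)
    # omega = 0: only the visited state's column changes, and its
    # increments sum to zero (REINFORCE identity)
    inc_trans <- P2$b_trans - P$b_trans
    expect_equal(sum(inc_trans[, s]), 0, tolerance = 1e-12)
    expect_equal(inc_trans[, -s], matrix(0, 6, 42), ignore_attr = TRUE)
    expect_equal(sum(P2$b_arm - P$b_arm), 0, tolerance = 1e-12)
  }
})

test_that("with zero signal and zero forgetting nothing changes", {
  spec <- model_spec("M3")
  P <- random_propensities(seed = 9)
  probs <- action_probabilities(total_propensity(spec, P, 2, 3), 3)
  P2 <- apply_updates(spec, P, 2, 3, 4, probs, delta = 0,
                      params = model_params(0.5, 0.5, 0))
  expect_equal(P2$b_trans, P$b_trans)
  expect_equal(P2$b_arm, P$b_arm)
  expect_equal(P2$b_n1, P$b_n1)
  expect_equal(P2$V, P$V)
})

test_that("with zero signal every component decays by exactly (1 - omega)", {
  spec <- model_spec("M3")
  P <- random_propensities(seed = 10)
  probs <- action_probabilities(total_propensity(spec, P, 2, 3), 3)
  P2 <- apply_updates(spec, P, 2, 3, 4, probs, delta = 0,
                      params = model_params(0.5, 0.5, 0.01))
  expect_equal(P2$b_trans, P$b_trans * 0.99)
  expect_equal(P2$b_arm, P$b_arm * 0.99)
  expect_equal(P2$b_n1, P$b_n1 * 0.99)
  expect_equal(P2$b_n2, P$b_n2 * 0.99)
  expect_equal(P2$V, P$V * 0.99)
})

test_that("alpha = 0 with forgetting decays all preferences geometrically to zero", {
  spec <- model_spec("M3")
  params <- model_params(0, 0.5, 0.015)
  sched <- tiny_schedule(1L, explore_sessions = 1L, explore_rewards = 10L)
  init <- random_propensities(seed = 11)
  set.seed(12)
  ep <- wtrackrl:::run_one_episode(spec, params, sched, init = init)
  n <- length(ep$sim$arm)
  f <- (1 - 0.015)^n
  expect_equal(ep$propensities$b_trans, init$b_trans * f, tolerance = 1e-10)
  expect_equal(ep$propensities$b_arm, init$b_arm * f, tolerance = 1e-10)
  expect_equal(ep$propensities$b_n1, init$b_n1 * f, tolerance = 1e-10)
  expect_equal(ep$propensities$V, init$V * f, tolerance = 1e-10)
})

test_that("neighbor propensity terms respect track edges", {
  spec <- model_spec("M3")
  P <- propensity_set(b_n1 = 1)
  # interior arm: both neighbors
  expect_equal(total_propensity(spec, P, 0, 3), c(0, 1, 0, 1, 0, 0))
  # edge arm: only the in-range side
  expect_equal(total_propensity(spec, P, 0, 1), c(0, 1, 0, 0, 0, 0))
  expect_equal(total_propensity(spec, P, 0, 6), c(0, 0, 0, 0, 1, 0))
  P2 <- propensity_set(b_n2 = 1)
  expect_equal(total_propensity(spec, P2, 0, 2), c(0, 0, 0, 1, 0, 0))
  # from the rest box no neighbor term applies
  expect_equal(total_propensity(spec, P2, 0, 0), rep(0, 6))
  # M1 with all-zero propensities is indifferent
  expect_equal(total_propensity(model_spec("M1"), propensity_set(), 0, 3),
               rep(0, 6))
})

test_that("model variants nest: shared components update identically", {
  # M3 with zero neighbor terms produces M2's policy, and its updates to
  # the shared components match M2's exactly; likewise M2 with zero arm
  # preference nests M1.
  params <- model_params(0.4, 0.6, 0.008)
  set.seed(13)
  for (i in 1:10) {
    P <- random_propensities(seed = 20 + i)
    P$b_n1 <- 0; P$b_n2 <- 0
    prev <- sample(1:6, 1); cur <- sample(setdiff(1:6, prev), 1)
    m2 <- total_propensity(model_spec("M2"), P, prev, cur)
    m3 <- total_propensity(model_spec("M3"), P, prev, cur)
    expect_equal(m2, m3)
    probs <- action_probabilities(m3, cur)
    chosen <- sample(which(probs > 0), 1)
    delta <- rnorm(1)
    u2 <- apply_updates(model_spec("M2"), P, prev, cur, chosen, probs,
                        delta, params)
    u3 <- apply_updates(model_spec("M3"), P, prev, cur, chosen, probs,
                        delta, params)
    expect_equal(u2$b_trans, u3$b_trans)
    expect_equal(u2$b_arm, u3$b_arm)
    expect_equal(u2$V, u3$V)

    Q <- P; Q$b_arm <- numeric(6)
    m1 <- total_propensity(model_spec("M1"), Q, prev, cur)
    m2b <- total_propensity(model_spec("M2"), Q, prev, cur)
    expect_equal(m1, m2b)
    u1 <- apply_updates(model_spec("M1"), Q, prev, cur, chosen, probs,
                        delta, params)
    u2b <- apply_updates(model_spec("M2"), Q, prev, cur, chosen, probs,
                         delta, params)
    expect_equal(u1$b_trans, u2b$b_trans)
    expect_equal(u1$V, u2b$V)
  }
})

test_that("the compiled simulator matches the single-step reference exactly", {
  spec <- model_spec("M3")
  params <- model_params(0.4, 0.3, 0.01)
  cg <- contingency(c(2, 3, 4))
  sch <- schedule(list(wtrackrl:::wt_phase("alt", cg, 3L, 6L, 1L)))
  set.seed(42)
  ep <- wtrackrl:::run_one_episode(spec, params, sch)
  tr <- wtrackrl:::sim_to_trajectory(ep$sim, sch)
  P <- propensity_set()
  st <- task_state(cg)
  prev <- 0L; cur <- 0L
  for (i in seq_len(nrow(tr))) {
    if (i > 1 && tr$session[i] != tr$session[i - 1]) {
      prev <- 0L; cur <- 0L; st <- task_state(cg)
    }
    probs <- action_probabilities(total_propensity(spec, P, prev, cur), cur)
    a <- tr$arm[i]
    stp <- alternation_step(st, a); st <- stp$state
    expect_identical(as.integer(stp$rewarded), tr$rewarded[i])
    delta <- prediction_error(as.numeric(stp$rewarded),
                              P$V[state_index(prev, cur)],
                              P$V[state_index(cur, a)], params$gamma)
    P <- apply_updates(spec, P, prev, cur, a, probs, delta, params)
    prev <- cur; cur <- a
  }
  expect_equal(P$b_trans, ep$propensities$b_trans, tolerance = 1e-12)
  expect_equal(P$b_arm, ep$propensities$b_arm, tolerance = 1e-12)
  expect_equal(P$b_n1, ep$propensities$b_n1, tolerance = 1e-12)
  expect_equal(P$b_n2, ep$propensities$b_n2, tolerance = 1e-12)
  expect_equal(P$V, ep$propensities$V, tolerance = 1e-12)
})

test_that("simulation is reproducible for a given seed", {
  sched <- tiny_schedule(2L)
  spec <- model_spec("M3")
  params <- model_params(0.5, 0.5, 0.005)
  a <- run_agent(spec, params, sched, n_repeats = 2L, seed = 77L)
  b <- run_agent(spec, params, sched, n_repeats = 2L, seed = 77L)
  expect_identical(a$trajectories, b$trajectories)
  # repeat k depends only on seed + k: a longer run shares its prefix
  c3 <- run_agent(spec, params, sched, n_repeats = 3L, seed = 77L)
  expect_identical(c3$trajectories[[2L]]$arm, a$trajectories[[2L]]$arm)
})

test_that("forced trajectories drive updates while leaving metrics identical", {
  spec <- model_spec("M3")
  params <- model_params(0.5, 0.5, 0.005)
  P0 <- propensity_set()
  # empty sequence is a no-op
  expect_equal(force_trajectory(spec, P0, params, integer(0)), P0)
  # a neighbor-rich forced exploration raises the one-away preference
  v <- rep(c(1:6, 5:2), 10)
  P1 <- force_trajectory(spec, P0, params, v)
  expect_gt(P1$b_n1, P0$b_n1)
  # repeats are rejected
  expect_error(force_trajectory(spec, P0, params, c(1, 1, 2)), "repeats")
  # the forced period reproduces the input's visit metrics exactly
  sched <- tiny_schedule(1L)
  cfg <- synthetic_rat_config(seed = 21L, explore_sessions = 4L,
                              rewards_per_session = 15L)
  ex <- gen_exploration(cfg)
  res <- run_agent(spec, params, sched, n_repeats = 1L, seed = 3L,
                   forced_explore = ex$arm,
                   forced_explore_sessions = ex$session)
  sim_ex <- res$trajectories[[1L]]
  sim_ex <- sim_ex[sim_ex$phase == "explore", ]
  expect_identical(sim_ex$arm, ex$arm)
  expect_identical(large_sweep_rate(sim_ex), large_sweep_rate(ex))
  expect_equal(preference_stats(sim_ex)$neighbor_freq,
               preference_stats(ex)$neighbor_freq)
})
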