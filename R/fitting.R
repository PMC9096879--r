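# Approximate Bayesian computation fitting of (alpha, gamma, omega) per
# animal, by matching smoothed inbound/outbound error curves between the
# animal and the average of many stochastic model repeats.

#' Default fitting bounds
#'
#' alpha in \[0, 1\], gamma in \[0, 0.99\], omega in \[0.001, 0.015\].
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function() {
  list(alpha = c(0, 1), gamma = c(0, 0.99), omega = c(0.001, 0.015))
}

#' Simulated-annealing configuration
#'
#' Geometric cooling from `t0` by `cooling` per step for `steps` steps;
#' Gaussian proposals with per-parameter width `width_frac` times the bound
#' range, reflected at the bounds.
#'
#' @param t0 Initial temperature (default 1).
#' @param cooling Multiplicative cooling factor per step (default 0.95).
#' @param steps Annealing steps per restart (default 400).
#' @param width_frac Proposal SD as a fraction of each bound range
#'   (default 0.1).
#' @return A list of class `wt_anneal_config`.
#' @export
anneal_config <- function(t0 = 1, cooling = 0.95, steps = 400L,
                          width_frac = 0.1) {
  stopifnot(t0 > 0, cooling > 0, cooling < 1, steps >= 1, width_frac > 0)
  structure(list(t0 = t0, cooling = cooling, steps = as.integer(steps),
                 width_frac = width_frac),
            class = "wt_anneal_config")
}

#' Summarize an animal's data for fitting
#'
#' Extracts from one rat's trajectory everything the ABC objective needs:
#' the exploration visit sequence (used to force the model's initial
#' conditions), and for each fitted contingency the smoothed inbound and
#' outbound error-likelihood curves in trial-type index.
#'
#' @param traj Trajectory data frame for one rat (exploration and
#'   alternation rows).
#' @param fit_contingencies Contingency indices to fit (default `c(2, 3)`,
#'   the most representative contingencies: they follow other simple ones
#'   and precede the arm-skipping contingency).
#' @param error_sd Gaussian SD (in errors) for the fitted curves
#'   (default 2.25).
#' @return A list of class `wt_animal_summary`.
#' @export
animal_summary <- function(traj, fit_contingencies = c(2L, 3L),
                           error_sd = 2.25) {
  traj <- ensure_contingency_index(traj)
  ex <- traj[traj$phase == "explore", , drop = FALSE]
  if (nrow(ex) == 0L) stop("animal has no exploration data", call. = FALSE)
  curves <- lapply(fit_contingencies, function(i) {
    pc <- performance_curves(traj, i, error_sd = error_sd)
    list(inbound = gaussian_smooth(pc$inbound_raw, error_sd),
         outbound = gaussian_smooth(pc$outbound_raw, error_sd))
  })
  names(curves) <- as.character(fit_contingencies)
  structure(
    list(explore_visits = as.integer(ex$arm),
         explore_sessions = as.integer(ex$session),
         fit_contingencies = as.integer(fit_contingencies),
         curves = curves, error_sd = error_sd,
         rat_id = traj$rat_id[1L]),
    class = "wt_animal_summary"
  )
}

# truncate or pad (repeating the last value) a vector to length n
fit_to_length <- function(x, n) {
  if (length(x) >= n) return(x[seq_len(n)])
  if (length(x) == 0L) return(rep(0.5, n))   # no trials of this type
  c(x, rep(x[length(x)], n - length(x)))
}

# average per-type raw error series over raw repeats, aligned to the
# animal's trial counts, for one contingency index with center arm `center`
average_model_errors <- function(sims, cont_index, center, n_in, n_out) {
  acc_in <- numeric(n_in)
  acc_out <- numeric(n_out)
  for (sim in sims) {
    from <- raw_from_arms(sim)
    sel <- which(!is.na(sim$cont) & sim$cont == cont_index)
    err <- 1L - sim$rewarded[sel]
    outb <- from[sel] == center
    acc_in <- acc_in + fit_to_length(err[!outb], n_in)
    acc_out <- acc_out + fit_to_length(err[outb], n_out)
  }
  list(inbound = acc_in / length(sims), outbound = acc_out / length(sims))
}

#' ABC fitting objective
#'
#' Runs `n_repeats` seeded episodes of the model — exploration forced to
#' the animal's own visit sequence, then free play through the schedule up
#' to the last fitted contingency — and returns the fitting error: the RMS
#' difference between the animal's and the model-average smoothed inbound
#' error curves plus the RMS difference for outbound curves, pooled over
#' the fitted contingencies with equal weighting. Model repeats are
#' truncated or padded to the animal's per-type trial counts before
#' averaging. The same base seed is used for every parameter evaluation
#' (common random numbers), so the objective is deterministic given
#' (params, seed).
#'
#' @param animal A [animal_summary()].
#' @param spec A [model_spec()].
#' @param params A [model_params()] (or list with alpha, gamma, omega).
#' @param sched The task [schedule()]; phases after the last fitted
#'   contingency are dropped automatically.
#' @param n_repeats Model repeats averaged per evaluation (default 200).
#' @param seed Base seed shared across evaluations.
#' @return The scalar fitting error (rms inbound + rms outbound).
#' @export
abc_objective <- function(animal, spec, params, sched, n_repeats = 200L,
                          seed = 1L) {
  stopifnot(inherits(animal, "wt_animal_summary"))
  if (!inherits(params, "wt_params")) {
    params <- model_params(params$alpha, params$gamma, params$omega)
  }
  sub_sched <- truncate_schedule(sched, max(animal$fit_contingencies))
  validate_forced(animal$explore_visits, animal$explore_sessions)
  phases <- phases_for_cpp(sub_sched, animal$explore_visits,
                           animal$explore_sessions)
  sims <- run_raw_episodes(spec, params, phases, n_repeats, seed)
  centers <- vapply(sub_sched$phases, function(p) {
    if (is.null(p$contingency)) NA_integer_ else p$contingency$center
  }, integer(1))
  idx <- vapply(sub_sched$phases, function(p) p$contingency_index, integer(1))
  diffs_in <- c(); diffs_out <- c()
  for (ci in animal$fit_contingencies) {
    ref <- animal$curves[[as.character(ci)]]
    center <- centers[match(ci, idx)]
    avg <- average_model_errors(sims, ci, center,
                                length(ref$inbound), length(ref$outbound))
    diffs_in <- c(diffs_in,
                  gaussian_smooth(avg$inbound, animal$error_sd) - ref$inbound)
    diffs_out <- c(diffs_out,
                   gaussian_smooth(avg$outbound, animal$error_sd) - ref$outbound)
  }
  sqrt(mean(diffs_in^2)) + sqrt(mean(diffs_out^2))
}

# vectorized reflection of proposals back into [lo, hi]
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  stopifnot(all(width > 0))
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

anneal_once <- function(objective, bounds, cfg, seed) {
  set.seed(seed)
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  cur <- lo + stats::runif(3) * (hi - lo)
  cur_err <- objective(cur)
  best <- cur; best_err <- cur_err
  temp <- cfg$t0
  width <- cfg$width_frac * (hi - lo)
  trace <- numeric(cfg$steps)
  for (step in seq_len(cfg$steps)) {
    prop <- reflect_into(cur + stats::rnorm(3, 0, width), lo, hi)
    err <- objective(prop)
    if (err < cur_err || stats::runif(1) < exp((cur_err - err) / temp)) {
      cur <- prop; cur_err <- err
    }
    if (err < best_err) { best <- prop; best_err <- err }
    trace[step] <- best_err
    temp <- temp * cfg$cooling
  }
  list(params = stats::setNames(best, names(bounds)), rms = best_err,
       trace = trace)
}

#' Fit a model to one animal by ABC with simulated annealing
#'
#' Minimizes [abc_objective()] over (alpha, gamma, omega) within bounds
#' using simulated annealing, restarted `n_restarts` times (at least 4)
#' from different random initial conditions. Every objective evaluation
#' uses the same simulation seed (common random numbers). The restart with
#' the minimal fitting error wins.
#'
#' @param animal A [animal_summary()].
#' @param spec A [model_spec()].
#' @param sched The task [schedule()].
#' @param bounds Parameter bounds, as [default_bounds()].
#' @param n_restarts Annealing restarts (default 4; fewer is an error).
#' @param n_repeats Model repeats per objective evaluation (default 200).
#' @param anneal An [anneal_config()].
#' @param seed Integer seed: `seed` drives the simulations (common across
#'   evaluations), `seed + restart` drives each restart's proposals.
#' @return A list of class `wt_fit_result`: `params` ([model_params()]),
#'   `rms`, `restart_errors` (per-restart params and rms), `seed`,
#'   `fit_contingencies`, `n_repeats`, `anneal`.
#' @export
fit_animal <- function(animal, spec, sched, bounds = default_bounds(),
                       n_restarts = 4L, n_repeats = 200L,
                       anneal = anneal_config(), seed = 1L) {
  if (n_restarts < 4L) stop("at least 4 restarts are required", call. = FALSE)
  objective <- function(theta) {
    abc_objective(animal, spec,
                  list(alpha = theta[1L], gamma = theta[2L],
                       omega = theta[3L]),
                  sched, n_repeats = n_repeats, seed = seed)
  }
  restarts <- lapply(seq_len(n_restarts), function(r) {
    anneal_once(objective, bounds, anneal, seed = seed + 1000L * r)
  })
  errs <- vapply(restarts, `[[`, numeric(1), "rms")
  if (!any(is.finite(errs))) stop("fit failed: no valid evaluations",
                                  call. = FALSE)
  best <- restarts[[which.min(errs)]]
  structure(
    list(params = model_params(best$params[["alpha"]], best$params[["gamma"]],
                               best$params[["omega"]]),
         rms = best$rms, restart_errors = restarts, seed = seed,
         fit_contingencies = animal$fit_contingencies,
         n_repeats = n_repeats, anneal = anneal),
    class = "wt_fit_result"
  )
}

#' @export
print.wt_fit_result <- function(x, ...) {
  cat(sprintf("<fit: alpha=%.3f gamma=%.3f omega=%.4f rms=%.4f (%d restarts)>\n",
              x$params$alpha, x$params$gamma, x$params$omega, x$rms,
              length(x$restart_errors)))
  invisible(x)
}

#' Repeated fits of one animal
#'
#' Runs `n_fits` independent [fit_animal()] calls (different seeds) and
#' reports the median and interquartile range of each parameter, the
#' convention for displaying per-animal fit uncertainty.
#'
#' @inheritParams fit_animal
#' @param n_fits Number of independent fits (default 20).
#' @return A list with `fits`, `median` and `iqr` (named 3-vectors).
#' @export
fit_animal_batch <- function(animal, spec, sched, n_fits = 20L, seed = 1L,
                             ...) {
  fits <- lapply(seq_len(n_fits), function(i) {
    fit_animal(animal, spec, sched, seed = seed + 10000L * i, ...)
  })
  pm <- t(vapply(fits, function(f) {
    c(alpha = f$params$alpha, gamma = f$params$gamma, omega = f$params$omega)
  }, numeric(3)))
  list(fits = fits, median = apply(pm, 2L, stats::median),
       iqr = apply(pm, 2L, stats::IQR))
}

#' Parameters maximizing obtained reward
#'
#' Grid search (optionally followed by one local refinement pass around the
#' best cell) for the (alpha, gamma, omega) maximizing the mean
#' alternation-phase reward over seeded repeats of the full schedule. Ties
#' break towards the lowest grid index, so degenerate tasks return a
#' deterministic answer.
#'
#' @param spec A [model_spec()].
#' @param sched The task [schedule()].
#' @param bounds Parameter bounds, as [default_bounds()].
#' @param grid_n Grid points per parameter (default 5).
#' @param n_repeats Repeats per grid cell (default 10).
#' @param seed Base seed (common random numbers across cells).
#' @param refine If `TRUE` (default), rerun the grid once on a halved range
#'   centered on the coarse optimum.
#' @return A list with `params` ([model_params()]), `reward` (mean reward
#'   per alternation visit) and `grid` (data frame of all evaluations).
#' @export
reward_maximizing_params <- function(spec, sched, bounds = default_bounds(),
                                     grid_n = 5L, n_repeats = 10L, seed = 1L,
                                     refine = TRUE) {
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  eval_grid <- function(lo, hi) {
    axes <- lapply(seq_len(3L), function(j) seq(lo[j], hi[j],
                                                length.out = grid_n))
    cells <- expand.grid(alpha = axes[[1L]], gamma = axes[[2L]],
                         omega = axes[[3L]], KEEP.OUT.ATTRS = FALSE)
    cells$reward <- vapply(seq_len(nrow(cells)), function(i) {
      res <- run_agent(spec, as.list(cells[i, 1:3]), sched,
                       n_repeats = n_repeats, seed = seed)
      mean_alternation_reward(res$trajectories)
    }, numeric(1))
    cells
  }
  grid <- eval_grid(lo, hi)
  best <- grid[which.max(grid$reward), ]    # which.max: lowest index on ties
  if (refine) {
    span <- (hi - lo) / (grid_n - 1L)
    ctr <- as.numeric(best[1:3])
    lo2 <- pmax(lo, ctr - span); hi2 <- pmin(hi, ctr + span)
    grid2 <- eval_grid(lo2, hi2)
    best2 <- grid2[which.max(grid2$reward), ]
    if (best2$reward > best$reward) best <- best2
    grid <- rbind(grid, grid2)
  }
  list(params = model_params(best$alpha, best$gamma, best$omega),
       reward = best$reward, grid = grid)
}
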