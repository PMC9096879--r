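# Readers/writers for the trajectory CSV and result formats, and the
# top-level pipeline tying the modules together.

TRAJ_COLUMNS <- c("rat_id", "phase", "contingency_label", "session",
                  "trial", "arm", "rewarded")

#' Read a trajectory table
#'
#' Reads and validates the canonical trajectory CSV (comma-separated,
#' UTF-8, header mandatory): columns `rat_id`, `phase` (`explore`/`alt`),
#' `contingency_label`, `session`, `trial`, `arm` (1-6), `rewarded` (0/1).
#' Rows are ordered by (rat, session, trial); parse errors name the
#' offending data row.
#'
#' @param path CSV file path.
#' @return A validated trajectory data frame with a reconstructed
#'   `contingency` index column.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRAJ_COLUMNS, names(df))
  if (length(missing)) {
    stop("missing trajectory columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$contingency_label <- as.character(df$contingency_label)
  df$contingency_label[is.na(df$contingency_label)] <- ""
  if (nrow(df) == 0L) return(ensure_contingency_index(df))
  bad_arm <- which(is.na(df$arm) | df$arm < 1L | df$arm > 6L)
  if (length(bad_arm)) {
    stop("invalid arm id at data row ", bad_arm[1L], call. = FALSE)
  }
  bad_phase <- which(!df$phase %in% c("explore", "alt"))
  if (length(bad_phase)) {
    stop("unknown phase at data row ", bad_phase[1L], call. = FALSE)
  }
  bad_rew <- which(!df$rewarded %in% c(0L, 1L))
  if (length(bad_rew)) {
    stop("rewarded must be 0/1 at data row ", bad_rew[1L], call. = FALSE)
  }
  grp <- paste(df$rat_id, df$phase, df$session)
  new_grp <- c(TRUE, grp[-1L] != grp[-length(grp)])
  step <- c(1L, diff(df$trial))
  bad_trial <- which(!new_grp & step != 1L)
  if (length(bad_trial)) {
    stop("non-monotone trial index at data row ", bad_trial[1L],
         call. = FALSE)
  }
  df <- df[order(df$rat_id), , drop = FALSE]   # stable: keeps session order
  rownames(df) <- NULL
  ensure_contingency_index(df)
}

#' @rdname read_trajectories
#' @param traj Trajectory data frame to write.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(traj[, TRAJ_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Split a combined trajectory table by rat
#'
#' @param traj Trajectory data frame with a `rat_id` column.
#' @return Named list of per-rat data frames, in order of appearance.
#' @export
split_rats <- function(traj) {
  split(traj, factor(traj$rat_id, levels = unique(traj$rat_id)))
}

#' Write cohort ground truth as JSON
#'
#' @param cohort A `wt_cohort` from [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj_path <- file.path(dir, "trajectories.csv")
  truth_path <- file.path(dir, "ground_truth.json")
  write_trajectories(cohort$trajectories, traj_path)
  jsonlite::write_json(cohort$ground_truth, truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(traj_path, truth_path))
}

#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates the standard analysis sequence on a cohort of trajectories:
#' 1. exploratory preference statistics per rat and population randomness
#'    tests (max arm probability vs. uniform null; neighbor frequency vs.
#'    arm-probability-preserving null; inertia vs. transition-preserving
#'    null), Bonferroni-corrected over the three tests;
#' 2. per-rat M3 fits to the fitted contingencies;
#' 3. rank-order variance explained between model and animal reward rates,
#'    on the fitted and (where present) the unfitted contingencies, and a
#'    median split of the animals by model reward rate;
#' 4. large-sweep and direction-alternation metrics per rat.
#'
#' Every stage is seeded from `seed`, so reruns reproduce the results
#' exactly.
#'
#' @param traj Combined trajectory data frame (e.g. a generated cohort or
#'   [read_trajectories()] output).
#' @param sched The [schedule()] the cohort was run on.
#' @param fit_contingencies Contingency indices to fit (default `c(2, 3)`).
#' @param n_draws Null draws per randomness test (default 10000).
#' @param n_repeats Model repeats per objective evaluation (default 200).
#' @param n_restarts Annealing restarts per fit (default 4).
#' @param anneal An [anneal_config()].
#' @param seed Integer master seed.
#' @param fit If `FALSE`, skip the model-fitting stages (stages 2-3).
#' @return A list of per-stage results.
#' @export
run_pipeline <- function(traj, sched, fit_contingencies = c(2L, 3L),
                         n_draws = 10000L, n_repeats = 200L,
                         n_restarts = 4L, anneal = anneal_config(),
                         seed = 1L, fit = TRUE) {
  traj <- ensure_contingency_index(traj)
  rats <- split_rats(traj)
  explore <- lapply(rats, function(r) r[r$phase == "explore", , drop = FALSE])

  stats_tests <- list(
    max_arm_prob = list(stat = function(tr) preference_stats(tr)$max_arm_prob,
                        mode = "uniform"),
    neighbor_freq = list(stat = function(tr) preference_stats(tr)$neighbor_freq,
                         mode = "arm_probs"),
    inertia = list(stat = function(tr) preference_stats(tr)$inertia,
                   mode = "transitions"))
  randomness <- lapply(seq_along(stats_tests), function(k) {
    tst <- stats_tests[[k]]
    phi <- cohort_randomness_evidence(explore, tst$stat, tst$mode,
                                      n_draws = n_draws,
                                      seed = seed + 7000L * k)
    list(phi = phi,
         population_p = population_randomness_test(phi, seed = seed + k))
  })
  names(randomness) <- names(stats_tests)
  out <- list(
    seed = seed,
    preference = lapply(explore, preference_stats),
    randomness = randomness,
    bonferroni_threshold = 0.05 / 3,
    sweeps = vapply(rats, function(r) {
      large_sweep_rate(r[r$phase == "explore", , drop = FALSE])
    }, numeric(1)),
    direction_alternation = vapply(rats, function(r) {
      direction_alternation_rate(r[r$phase == "alt", , drop = FALSE],
                                 smooth_sd = 0)$rate
    }, numeric(1)),
    reward_rates = lapply(rats, reward_rates))

  if (fit) {
    spec <- model_spec("M3")
    fits <- lapply(seq_along(rats), function(i) {
      fit_animal(animal_summary(rats[[i]], fit_contingencies), spec, sched,
                 n_restarts = n_restarts, n_repeats = n_repeats,
                 anneal = anneal, seed = seed + 31L * i)
    })
    names(fits) <- names(rats)
    out$fits <- fits

    animal_fit_rate <- vapply(rats, function(r) {
      rr <- reward_rates(r)
      mean(rr[fit_contingencies])
    }, numeric(1))
    model_fit_rate <- vapply(seq_along(rats), function(i) {
      an <- animal_summary(rats[[i]], fit_contingencies)
      sub <- truncate_schedule(sched, max(fit_contingencies))
      res <- run_agent(spec, fits[[i]]$params, sub, n_repeats = 20L,
                       seed = seed + 77L * i,
                       forced_explore = an$explore_visits,
                       forced_explore_sessions = an$explore_sessions)
      vals <- unlist(lapply(res$trajectories, function(tr) {
        tr$rewarded[!is.na(tr$contingency) &
                      tr$contingency %in% fit_contingencies]
      }))
      mean(vals)
    }, numeric(1))
    out$rank_r2_fit <- rank_order_r2(model_fit_rate, animal_fit_rate)

    all_idx <- sort(unique(traj$contingency[!is.na(traj$contingency)]))
    unfit_idx <- setdiff(all_idx, fit_contingencies)
    if (length(unfit_idx)) {
      animal_unfit_rate <- vapply(rats, function(r) {
        mean(reward_rates(r)[unfit_idx])
      }, numeric(1))
      out$rank_r2_unfit <- rank_order_r2(model_fit_rate, animal_unfit_rate)
      out$median_split <- median_split_compare(model_fit_rate,
                                               animal_unfit_rate)
    }
  }
  out
}

#' Write pipeline results as JSON
#'
#' Serializes the scalar and vector results of [run_pipeline()] (fit
#' parameters, p-values, metrics) along with the seed that produced them.
#'
#' @param results A [run_pipeline()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pipeline_results <- function(results, path) {
  slim <- list(
    seed = results$seed,
    bonferroni_threshold = results$bonferroni_threshold,
    randomness = lapply(results$randomness, function(r) {
      list(phi = as.list(r$phi), population_p = r$population_p)
    }),
    sweeps = as.list(results$sweeps),
    direction_alternation = as.list(results$direction_alternation),
    reward_rates = lapply(results$reward_rates, as.list))
  if (!is.null(results$fits)) {
    slim$fits <- lapply(results$fits, function(f) {
      list(alpha = f$params$alpha, gamma = f$params$gamma,
           omega = f$params$omega, rms = f$rms, seed = f$seed)
    })
    slim$rank_r2_fit <- results$rank_r2_fit
    slim$rank_r2_unfit <- results$rank_r2_unfit
    if (!is.null(results$median_split)) {
      slim$median_split <- results$median_split[c("mean_high", "mean_low",
                                                  "p")]
    }
  }
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
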