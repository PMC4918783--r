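# Multi-trial, multi-run experiments and their summary metrics.

#' Run one trial
#'
#' Loops over the task horizon: evaluate every policy from the current belief,
#' form the precision-weighted policy posterior, sample the next action from
#' its per-step control marginal (restricted to feasible controls), step the
#' environment, sample an outcome and update the belief. Policies are
#' re-evaluated from scratch at every step, so the agent can abandon a policy
#' mid-trial.
#'
#' @param task a `maze_task`.
#' @param belief trial-start belief vector.
#' @param env an `env_state` positioned at the trial start.
#' @return a list: `record` (a trial record with executed `actions`,
#'   `outcomes`, sweep counts overall and by decision-point tag, the
#'   end-of-trial reward indicator and utility, the trial-start and
#'   end-of-trial context beliefs and the per-step most probable policy) and
#'   `belief`/`env` carrying the final state.
#' @export
run_trial <- function(task, belief, env) {
  h <- task$horizon
  actions <- outcomes <- policy_trace <- integer(h)
  sweep_tags <- character(0)
  ctx_start <- context_marginal(belief, task)
  for (k in seq_len(h)) {
    ev <- evaluate_policies(belief, task, from_step = k)
    post <- policy_posterior(ev$total, task$params$gamma)
    feas <- feasible_controls(task, env$location)
    a <- select_action(post, task$policies, k, feas)
    env <- env_step(env, a, task)
    o <- sample_outcome(env, task)
    belief <- bayes_update(belief, a, o, task)
    actions[k] <- a
    outcomes[k] <- o
    policy_trace[k] <- which.max(post)
    if (isTRUE(attr(env, "sweep"))) {
      sweep_tags <- c(sweep_tags, attr(env, "sweep_tag"))
    }
  }
  last_cue <- outcome_cue(outcomes[h], task)
  record <- list(
    actions = actions,
    outcomes = outcomes,
    sweeps = length(sweep_tags),
    sweeps_easy = sum(sweep_tags == "easy"),
    sweeps_costly = sum(sweep_tags == "costly"),
    reward_collected = last_cue %in% task$reward_cues,
    reward_utility = task$utilities[outcomes[h]],
    context_prior_start = ctx_start,
    context_posterior_end = context_marginal(belief, task),
    chosen_policy_trace = policy_trace,
    true_context = env$context
  )
  list(record = record, belief = belief, env = env)
}

# single seeded run over the full trial schedule; returns a list of records
run_one <- function(task, n_trials = task$n_trials) {
  env <- init_env(task)
  ctx_prior <- rep(1 / task$n_contexts, task$n_contexts)
  records <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    env <- advance_context(task$schedule, t, env, task$initial_context)
    belief <- initial_belief(task, ctx_prior)
    out <- run_trial(task, belief, env)
    records[[t]] <- out$record
    env <- out$env
    ctx_prior <- carryover_prior(context_marginal(out$belief, task),
                                 task$params$volatility)
  }
  records
}

#' Run a full simulation
#'
#' Executes `n_runs` independent runs of a named task over its trial schedule
#' (20, 30, 40 and 40 trials for `sim1`-`sim4`), with Bayesian belief
#' carryover between trials under the volatility prior, and aggregates the
#' per-trial metrics across runs. Run `r` is seeded with `seed + r`, so
#' results are reproducible and runs are independent.
#'
#' @param sim_name one of `"sim1"`, `"sim2"`, `"sim3"`, `"sim4"`.
#' @param n_runs number of independent runs to average over (the reference
#'   experiments use 1000).
#' @param seed base integer seed.
#' @param params an [agent_params()] object, or `NULL` for the task's
#'   calibrated defaults.
#' @param n_trials optional override of the task's trial count.
#' @param ... passed to [build_task()] (e.g. `usual_reward`, `diff` for
#'   `"sim4"`).
#' @return an `experiment_result`, see [compute_metrics()].
#' @export
run_simulation <- function(sim_name, n_runs = 1000L, seed = 1L,
                           params = NULL, n_trials = NULL, ...) {
  task <- build_task(sim_name, params, ...)
  if (!is.null(n_trials)) task$n_trials <- as.integer(n_trials)
  records <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    records[[r]] <- run_one(task)
  }
  compute_metrics(records, task, seed = seed)
}

#' Aggregate trial records into per-trial metrics
#'
#' Computes, per trial and averaged across runs: performance (fraction of runs
#' whose trial ends on a reward-cue outcome; its ceiling is the reward
#' reliability), mean end-of-trial utility and its normalisation by the best
#' achievable expected utility under the true context (`performance_utility`),
#' uncertainty (Shannon entropy of the trial-start context belief, normalised
#' by `ln K`), the fraction of runs executing at least one sweep
#' (`vte_fraction`, split by easy/costly decision point where the task tags
#' them), the sweep-count histogram (0 / 1 / 2-or-more), the mean sweep count,
#' and the mean end-of-trial posterior context belief (the belief heatmap).
#'
#' @param records list (one element per run) of lists of trial records from
#'   [run_trial()].
#' @param task the `maze_task` that produced them.
#' @param seed base seed used (stored for provenance).
#' @return an object of class `"experiment_result"`: list with `simulation`,
#'   `n_runs`, `n_trials`, `seed`, `trials` (a per-trial data.frame of the
#'   metrics above), `belief` (trials x contexts matrix) and `params`.
#' @export
compute_metrics <- function(records, task, seed = NA_integer_) {
  n_runs <- length(records)
  if (n_runs == 0) stop("no records to aggregate", call. = FALSE)
  n_trials <- length(records[[1L]])
  K <- task$n_contexts
  get_rt <- function(f) { # trials x runs
    m <- vapply(records, function(run) vapply(run, f, numeric(1)),
                numeric(n_trials))
    matrix(m, nrow = n_trials)
  }
  sweeps <- get_rt(function(rec) rec$sweeps)
  easy <- get_rt(function(rec) rec$sweeps_easy)
  costly <- get_rt(function(rec) rec$sweeps_costly)
  reward <- get_rt(function(rec) as.numeric(rec$reward_collected))
  utility <- get_rt(function(rec) rec$reward_utility)
  unc <- get_rt(function(rec) shannon_entropy(rec$context_prior_start) / log(K))
  true_ctx <- vapply(records[[1L]], function(rec) rec$true_context, numeric(1))
  belief <- matrix(0, n_trials, K, dimnames = list(NULL, task$contexts))
  for (run in records) {
    for (t in seq_len(n_trials)) {
      belief[t, ] <- belief[t, ] + run[[t]]$context_posterior_end
    }
  }
  belief <- belief / n_runs
  # best achievable expected end-of-trial utility per context (for the
  # normalised-utility performance variant used when both arms pay)
  best_utility <- vapply(seq_len(K), function(ctx) {
    arms <- setdiff(which(task$location_type == "real"), 1L)
    max(vapply(arms, function(l) {
      sum(task$A[, state_index(l, ctx, task)] * task$utilities)
    }, numeric(1)))
  }, numeric(1))
  rowmean <- function(m) rowMeans(m)
  trials <- data.frame(
    trial = seq_len(n_trials),
    true_context = true_ctx,
    performance = rowmean(reward),
    mean_utility = rowmean(utility),
    performance_utility = rowmean(utility) / pmax(best_utility[true_ctx], .PROB_FLOOR),
    uncertainty = rowmean(unc),
    vte_fraction = rowmean(sweeps >= 1),
    vte_fraction_easy = rowmean(easy >= 1),
    vte_fraction_costly = rowmean(costly >= 1),
    mean_sweeps = rowmean(sweeps),
    sweep0 = rowmean(sweeps == 0),
    sweep1 = rowmean(sweeps == 1),
    sweep2plus = rowmean(sweeps >= 2)
  )
  structure(list(simulation = task$name, n_runs = n_runs, n_trials = n_trials,
                 seed = seed, trials = trials, belief = belief,
                 params = task$params),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment '%s': %d trials x %d runs (seed %s)\n",
              x$simulation, x$n_trials, x$n_runs, x$seed))
  cat(sprintf("  overall performance %.3f, mean VTE fraction %.3f\n",
              mean(x$trials$performance), mean(x$trials$vte_fraction)))
  invisible(x)
}

#' Reward-grid sweep of the plentiful-reward task
#'
#' For every combination of the usual reward `c` and the high-reward
#' differential `diff`, runs the plentiful-reward protocol up to a probe trial
#' (trial 31 by default, the first trial after the final context change) and
#' records the mean number of forward sweeps executed on that trial. The
#' published grid uses 10,000 runs per cell; smaller counts give the same
#' landscape with wider Monte Carlo error.
#'
#' @param c_values numeric vector of usual-reward values.
#' @param diff_values numeric vector of nonnegative high-reward differentials.
#' @param n_runs runs per (c, diff) cell.
#' @param trial_index probe trial.
#' @param seed base integer seed.
#' @param params an [agent_params()] object.
#' @return a data.frame with columns `c`, `diff`, `mean_sweeps`,
#'   `vte_fraction`, `n_runs`, `trial`.
#' @export
sweep_reward_grid <- function(c_values = c(0, 0.5, 1, 1.5, 2),
                              diff_values = c(0, 1, 2, 3, 4),
                              n_runs = 10000L, trial_index = 31L, seed = 1L,
                              params = agent_params(gamma = 8,
                                                    imaginary_cost = -0.15)) {
  if (any(diff_values < 0)) stop("'diff_values' must be nonnegative", call. = FALSE)
  grid <- expand.grid(c = c_values, diff = diff_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mean_sweeps <- NA_real_
  grid$vte_fraction <- NA_real_
  for (i in seq_len(nrow(grid))) {
    task <- build_plentiful_tmaze(params, usual_reward = grid$c[i],
                                  diff = grid$diff[i])
    task$n_trials <- as.integer(trial_index)
    sweeps <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      set.seed(seed + r)
      run <- run_one(task)
      sweeps[r] <- run[[trial_index]]$sweeps
    }
    grid$mean_sweeps[i] <- mean(sweeps)
    grid$vte_fraction[i] <- mean(sweeps >= 1)
  }
  grid$n_runs <- n_runs
  grid$trial <- trial_index
  grid
}

#' Per-policy value diagnostics
#'
#' Dumps the extrinsic, epistemic and total value of every policy evaluated
#' from a belief — the quantities whose balance decides whether a sweep is
#' worth its cost.
#'
#' @param belief belief vector.
#' @param task a `maze_task`.
#' @param from_step first step still to execute.
#' @param file optional CSV path to write the table to.
#' @return a data.frame with one row per policy.
#' @export
policy_diagnostics <- function(belief, task, from_step = 1L, file = NULL) {
  ev <- evaluate_policies(belief, task, from_step)
  mask <- attr(task$policies, "imaginary_mask")
  df <- data.frame(
    policy = seq_len(nrow(task$policies)),
    controls = apply(task$policies, 1, paste, collapse = "-"),
    n_sweeps = rowSums(mask),
    extrinsic = rowSums(ev$extrinsic),
    epistemic = rowSums(ev$epistemic),
    total = ev$total,
    posterior = policy_posterior(ev$total, task$params$gamma)
  )
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
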