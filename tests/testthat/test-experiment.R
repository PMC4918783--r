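# Trial and experiment drivers plus their summary metrics.

test_that("a certain agent with perfect cues goes straight to the reward", {
  params <- agent_params(gamma = 60, reward_reliability = 1,
                         context_cue_reliability = 1)
  task <- build_two_arm_tmaze(params)
  set.seed(9)
  for (i in 1:5) {
    out <- run_trial(task, initial_belief(task, c(1, 0)), init_env(task, 1L))
    rec <- out$record
    expect_identical(rec$actions, c(2L, 2L, 2L))
    expect_true(rec$reward_collected)
    expect_identical(rec$sweeps, 0L)
  }
})

test_that("absorbed agents repeat the arm control to the end of the trial", {
  task <- build_two_arm_tmaze()
  set.seed(21)
  for (i in 1:20) {
    out <- run_trial(task, initial_belief(task), init_env(task, 1L))
    acts <- out$record$actions
    arm_step <- which(acts %in% c(2L, 3L))[1]
    if (!is.na(arm_step) && arm_step < length(acts)) {
      expect_true(all(acts[arm_step:length(acts)] == acts[arm_step]))
    }
    # sweep count conservation
    expect_identical(out$record$sweeps,
                     sum(acts %in% task$imaginary_controls))
  }
})

test_that("experiment results cover the published trial schedules", {
  lens <- c(sim1 = 20L, sim2 = 30L, sim3 = 40L, sim4 = 40L)
  for (name in names(lens)) {
    res <- run_simulation(name, n_runs = 2, seed = 3)
    expect_identical(res$n_trials, lens[[name]])
    expect_identical(nrow(res$trials), lens[[name]])
    expect_identical(dim(res$belief),
                     c(lens[[name]], build_task(name)$n_contexts))
    expect_true(all(res$trials$vte_fraction >= 0 &
                      res$trials$vte_fraction <= 1))
    expect_true(all(abs(rowSums(res$belief) - 1) < 1e-9))
  }
})

test_that("metrics hit their analytic bounds on constructed records", {
  task <- build_two_arm_tmaze()
  rec <- function(sweeps, reward, prior) {
    list(actions = c(2L, 2L, 2L), outcomes = rep(outcome_index(2, 1, task), 3),
         sweeps = sweeps, sweeps_easy = 0L, sweeps_costly = sweeps,
         reward_collected = reward, reward_utility = if (reward) 2 else -2,
         context_prior_start = prior, context_posterior_end = prior,
         chosen_policy_trace = c(1L, 1L, 1L), true_context = 1L)
  }
  records <- list(list(rec(0L, TRUE, c(0.5, 0.5))),
                  list(rec(2L, TRUE, c(0.5, 0.5))))
  m <- compute_metrics(records, task)
  expect_equal(m$trials$performance, 1)         # every run rewarded
  expect_equal(m$trials$uncertainty, 1)         # uniform prior
  expect_equal(m$trials$vte_fraction, 0.5)
  expect_equal(m$trials$sweep2plus, 0.5)
  records0 <- list(list(rec(0L, FALSE, c(1, 0))))
  m0 <- compute_metrics(records0, task)
  expect_equal(m0$trials$uncertainty, 0)
  expect_equal(m0$trials$vte_fraction, 0)
})

test_that("identical seeds reproduce bit-identical experiment results", {
  a <- run_simulation("sim1", n_runs = 5, seed = 123)
  b <- run_simulation("sim1", n_runs = 5, seed = 123)
  expect_identical(a$trials, b$trials)
  expect_identical(a$belief, b$belief)
  c2 <- run_simulation("sim1", n_runs = 5, seed = 124)
  expect_false(identical(a$trials, c2$trials))
})

test_that("the reward grid validates inputs and returns counts", {
  expect_error(sweep_reward_grid(diff_values = -1, n_runs = 1), "nonnegative")
  g <- sweep_reward_grid(c_values = c(0, 2), diff_values = 0, n_runs = 1,
                         trial_index = 3L, seed = 2)
  expect_identical(nrow(g), 2L)
  expect_true(all(g$mean_sweeps >= 0))
  expect_true(all(g$mean_sweeps == floor(g$mean_sweeps))) # single run: integers
})

test_that("policy diagnostics expose the extrinsic/epistemic split", {
  task <- build_two_arm_tmaze()
  d <- policy_diagnostics(initial_belief(task), task)
  expect_identical(nrow(d), 14L)
  expect_equal(d$total, d$extrinsic + d$epistemic, tolerance = 1e-10)
  expect_equal(sum(d$posterior), 1, tolerance = 1e-12)
  f <- tempfile(fileext = ".csv")
  policy_diagnostics(initial_belief(task), task, file = f)
  expect_true(file.exists(f))
  expect_identical(nrow(utils::read.csv(f)), 14L)
})
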