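# The belief-updating and expected-free-energy engine.

test_that("bayes_update matches hand-computed posteriors", {
  task <- build_two_arm_tmaze()
  # imagine left from an uncertain context, retrieve the 'reward there' cue:
  # posterior odds = prior odds x 0.85/0.15
  b <- initial_belief(task, c(0.5, 0.5))
  post <- bayes_update(b, action = 4L, observation = outcome_index(4, 3, task),
                       task = task)
  expect_equal(context_marginal(post, task), c(0.85, 0.15), tolerance = 1e-12)
  # move to the left arm and observe the neutral cue: likelihood 0.25 under
  # "reward left", 1 under "reward right"
  post2 <- bayes_update(b, action = 2L, observation = outcome_index(2, 2, task),
                        task = task)
  expect_equal(context_marginal(post2, task),
               c(0.5 * 0.25, 0.5) / (0.5 * 0.25 + 0.5), tolerance = 1e-12)
  # location is always resolved by the outcome's location component
  expect_equal(sum(post2[state_index(2, 1:2, task)]), 1)
})

test_that("bayes_update flags impossible observations", {
  task <- build_two_arm_tmaze()
  b <- initial_belief(task, c(1, 0))
  # reward cue at the right arm is impossible under a certain 'left' context
  expect_error(
    bayes_update(b, action = 3L, observation = outcome_index(3, 1, task), task),
    "zero likelihood")
})

test_that("bayes_update agrees with the joint-enumeration oracle", {
  set.seed(42)
  for (name in c("sim1", "sim3")) { # 10 and 44 hidden states
    task <- build_task(name)
    for (i in 1:10) {
      b <- as.numeric(rmultinom(1, 40, rep(1, task$n_states))) / 40
      u <- sample(task$n_controls, 1)
      pred <- as.numeric(task$B[[u]] %*% b)
      po <- as.numeric(task$A %*% pred)
      o <- sample(which(po > 1e-9), 1)
      expect_equal(bayes_update(b, u, o, task),
                   brute_force_posterior(b, u, o, task), tolerance = 1e-10)
    }
  }
})

test_that("belief propagation follows the transition model", {
  task <- build_two_arm_tmaze()
  b <- initial_belief(task, c(0.3, 0.7))
  expect_equal(propagate_belief(b, c(2L, 2L, 2L), 0, task), b)
  p1 <- propagate_belief(b, c(2L, 2L, 2L), 1, task)
  expect_equal(p1[state_index(2, 1, task)], 0.3) # context preserved
  expect_equal(p1[state_index(2, 2, task)], 0.7)
  # absorbing arm: further propagation is idempotent
  expect_equal(propagate_belief(b, c(2L, 2L, 2L), 2, task), p1)
  expect_error(propagate_belief(b, c(2L, 2L, 2L), 4, task), "tau")
})

test_that("outcome prediction reproduces the cue reliabilities", {
  task <- build_two_arm_tmaze()
  s <- numeric(task$n_states)
  s[state_index(2, 1, task)] <- 1  # left arm, context 'reward left'
  o <- outcome_prediction(s, task)
  expect_equal(o[outcome_index(2, 1, task)], 0.75)
  expect_equal(o[outcome_index(2, 2, task)], 0.25)
  expect_equal(sum(o), 1)
  set.seed(7)
  for (i in 1:10) {
    q <- as.numeric(rmultinom(1, 30, rep(1, task$n_states))) / 30
    expect_equal(sum(outcome_prediction(q, task)), 1, tolerance = 1e-12)
  }
})

test_that("extrinsic value is the expected log preference", {
  prefs <- normalize_preferences(c(2, -2))
  expect_equal(extrinsic_value(c(1, 0), prefs), prefs$log_preferences[1])
  expect_equal(extrinsic_value(c(0.5, 0.5), prefs), mean(prefs$log_preferences))
  expect_equal(extrinsic_value(c(0.75, 0.25), prefs),
               0.75 * (-log(1 + exp(-4))) + 0.25 * (-4 - log(1 + exp(-4))))
  expect_lte(extrinsic_value(c(0.75, 0.25), prefs), 0)
})

test_that("epistemic value has its analytic zeros and matches the KL form", {
  task <- build_two_arm_tmaze()
  # point-mass belief: nothing left to learn
  s <- numeric(task$n_states); s[1] <- 1
  expect_equal(epistemic_value(s, task), 0)
  # uninformative likelihood: all columns equal
  flatA <- matrix(1 / 4, 4, 6)
  set.seed(11)
  q <- as.numeric(rmultinom(1, 30, rep(1, 6))) / 30
  expect_equal(epistemic_value(q, flatA), 0, tolerance = 1e-12)
  # two equiprobable states under an identity likelihood: one full bit
  expect_equal(epistemic_value(c(0.5, 0.5), diag(2)), log(2))
  # random cases against the textbook expected-KL oracle
  for (i in 1:25) {
    q <- as.numeric(rmultinom(1, 50, rep(1, task$n_states))) / 50
    expect_equal(epistemic_value(q, task), kl_form_epistemic(q, task$A),
                 tolerance = 1e-10)
    expect_gte(epistemic_value(q, task), 0)
  }
})

test_that("epistemic value is invariant to state and outcome relabeling", {
  task <- build_two_arm_tmaze()
  set.seed(3)
  for (i in 1:10) {
    q <- as.numeric(rmultinom(1, 50, rep(1, task$n_states))) / 50
    ps <- sample(task$n_states)
    po <- sample(task$n_outcomes)
    A2 <- task$A[po, ps]
    expect_equal(epistemic_value(q[ps], A2), epistemic_value(q, task),
                 tolerance = 1e-10)
  }
})

test_that("policy quality decomposes into extrinsic plus epistemic value", {
  task <- build_two_arm_tmaze()
  b <- initial_belief(task, c(0.6, 0.4))
  pq <- policy_quality(b, task$policies[3, ], task)
  expect_equal(pq$per_tau_quality,
               pq$extrinsic_component + pq$epistemic_component, tolerance = 1e-10)
  expect_equal(pq$total_quality, sum(pq$per_tau_quality), tolerance = 1e-10)
  expect_true(all(pq$epistemic_component >= 0))
  # vectorised evaluation agrees with the per-policy path
  ev <- evaluate_policies(b, task)
  per <- vapply(seq_len(nrow(task$policies)), function(i) {
    policy_quality(b, task$policies[i, ], task)$total_quality
  }, numeric(1))
  expect_equal(ev$total, per, tolerance = 1e-10)
})

test_that("a certain agent ranks the direct rewarded-arm policy first", {
  task <- build_two_arm_tmaze()
  b <- initial_belief(task, c(1, 0)) # reward is on the left, and it knows
  ev <- evaluate_policies(b, task)
  best <- which.max(ev$total)
  expect_identical(as.integer(task$policies[best, ]), c(2L, 2L, 2L))
  # no residual uncertainty: every policy's epistemic component is zero
  expect_true(all(abs(ev$epistemic) < 1e-10))
})

test_that("policy posterior is a normalised softmax with the right limits", {
  q <- c(1, 0)
  expect_equal(policy_posterior(q, 0), c(0.5, 0.5))
  expect_equal(policy_posterior(q, 1), c(exp(1), 1) / (exp(1) + 1))
  expect_equal(sum(policy_posterior(rnorm(10), 2.5)), 1, tolerance = 1e-12)
  expect_equal(policy_posterior(q, 500)[1], 1, tolerance = 1e-12)
  expect_error(policy_posterior(c(1, NaN), 1), "non-finite")
})

test_that("action sampling follows the per-step control marginal", {
  task <- build_two_arm_tmaze()
  pols <- task$policies
  post <- numeric(nrow(pols)); post[1] <- 1 # point mass on [L, L, L]
  set.seed(1)
  expect_identical(select_action(post, pols, 1L, feasible_controls(task, 1L)),
                   as.integer(pols[1, 1]))
  # two policies with equal mass prescribing the same first control
  post2 <- numeric(nrow(pols)); post2[c(3, 4)] <- 0.5 # both start 'imagine left'
  expect_identical(select_action(post2, pols, 1L, feasible_controls(task, 1L)), 4L)
  # in an absorbing arm only the matching arm control is feasible
  expect_identical(feasible_controls(task, 2L), 2L)
  expect_identical(select_action(rep(1 / 14, 14), pols, 2L, 2L), 2L)
})

test_that("free energy bounds the negative log evidence, tight at the posterior", {
  task <- build_two_arm_tmaze()
  prior <- initial_belief(task, c(0.4, 0.6))
  u <- 4L
  o <- outcome_index(4, 3, task)
  evidence <- sum(task$A[o, ] * as.numeric(task$B[[u]] %*% prior))
  post <- bayes_update(prior, u, o, task)
  expect_equal(free_energy(post, prior, u, o, task), -log(evidence),
               tolerance = 1e-10)
  set.seed(5)
  for (i in 1:20) {
    q <- post + runif(task$n_states, 0, 0.2) * (post > 0)
    q <- q / sum(q)
    expect_gte(free_energy(q, prior, u, o, task), -log(evidence) - 1e-12)
  }
  # perturbing the exact posterior strictly increases free energy
  q <- post
  shift <- 0.05
  q[state_index(4, 1, task)] <- q[state_index(4, 1, task)] - shift
  q[state_index(4, 2, task)] <- q[state_index(4, 2, task)] + shift
  expect_gt(free_energy(q, prior, u, o, task), -log(evidence) + 1e-6)
})

test_that("with an identity likelihood the quality is a negative KL divergence", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    task <- identity_task(n, utilities = rnorm(n, sd = 2))
    q <- as.numeric(rmultinom(1, 60, runif(n) + 0.1)) / 60
    qual <- extrinsic_value(outcome_prediction(q, task), task$prefs) +
      epistemic_value(q, task$A)
    expect_equal(qual, -kl_div_ref(q, exp(task$logC)), tolerance = 1e-10)
  }
})

test_that("scaling utilities rescales extrinsic but not epistemic value", {
  p0 <- agent_params()
  task <- build_two_arm_tmaze(p0)
  b <- initial_belief(task, c(0.5, 0.5))
  ev <- evaluate_policies(b, task)
  task2 <- task
  task2$logC <- normalize_preferences(3 * task$utilities)$log_preferences
  ev2 <- evaluate_policies(b, task2)
  expect_equal(ev2$epistemic, ev$epistemic, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ev2$extrinsic, ev$extrinsic)))
})

test_that("consistent evidence drives the context marginal to certainty", {
  task <- build_two_arm_tmaze(agent_params(volatility = 0))
  b <- initial_belief(task, c(0.5, 0.5))
  prev <- 0.5
  for (i in 1:12) {
    b <- bayes_update(b, 4L, outcome_index(4, 3, task), task)
    cur <- context_marginal(b, task)[1]
    expect_gte(cur, prev)
    prev <- cur
    # re-anchor at the center for the next covert retrieval
    loc <- c(b[state_index(4, 1, task)], b[state_index(4, 2, task)])
    b <- initial_belief(task, loc / sum(loc))
  }
  expect_gt(prev, 0.999)
})
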