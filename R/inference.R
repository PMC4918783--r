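# Belief updating and expected free energy.
#
# Beliefs are categorical distributions over the hidden states of a task
# (location x context). For this discrete model family the exact recursive
# Bayesian filter is the fixed point of the variational scheme, so beliefs are
# updated exactly; the one-step free-energy functional is retained (see
# free_energy) as the variational oracle.

#' Initial belief state
#'
#' Builds the trial-start belief: a point mass on the center/home location
#' combined with a prior over contexts (uniform by default, the uninformative
#' first-trial prior).
#'
#' @param task a `maze_task`.
#' @param context_prior optional distribution over contexts.
#' @param location location index of the point mass (default 1, center).
#' @return numeric belief vector of length `task$n_states`.
#' @export
initial_belief <- function(task, context_prior = NULL, location = 1L) {
  if (is.null(context_prior)) {
    context_prior <- rep(1 / task$n_contexts, task$n_contexts)
  }
  stopifnot_prob(context_prior, "context_prior")
  b <- numeric(task$n_states)
  b[state_index(location, seq_len(task$n_contexts), task)] <- context_prior
  b
}

#' Context marginal of a belief
#'
#' @param belief numeric belief vector over hidden states.
#' @param task a `maze_task`.
#' @return distribution over contexts (belief summed over locations).
#' @export
context_marginal <- function(belief, task) {
  as.numeric(rowsum(belief, state_context(seq_along(belief), task)))
}

#' Exact Bayesian belief update
#'
#' One filtering step: predict through the transition matrix of the executed
#' control, then condition on the observed outcome,
#' `posterior(s') \propto P(o | s') sum_s P(s' | s, u) belief(s)`.
#'
#' @param belief numeric belief vector over hidden states.
#' @param action executed control index (or `NULL` for a pure conditioning
#'   step without a transition).
#' @param observation observed outcome index.
#' @param task a `maze_task`.
#' @return the posterior belief vector.
#' @export
bayes_update <- function(belief, action, observation, task) {
  pred <- if (is.null(action)) belief else as.numeric(task$B[[action]] %*% belief)
  lik <- task$A[observation, ]
  post <- lik * pred
  z <- sum(post)
  if (z <= .PROB_FLOOR) {
    loc <- outcome_location(observation, task)
    cue <- outcome_cue(observation, task)
    stop(sprintf(
      "observation %d (location '%s', cue '%s') has zero likelihood under the predicted state distribution",
      observation, task$locations[loc], task$cues[cue]), call. = FALSE)
  }
  post / z
}

#' Propagate a belief along a policy
#'
#' Predictive state distribution `tau` steps ahead under a policy:
#' `B[u_tau] ... B[u_1] belief` (no conditioning on future outcomes).
#'
#' @param belief numeric belief vector.
#' @param policy integer vector of control indices.
#' @param tau number of steps to propagate (0 returns the belief unchanged).
#' @param task a `maze_task`.
#' @return predictive state distribution.
#' @export
propagate_belief <- function(belief, policy, tau, task) {
  if (tau < 0 || tau > length(policy)) {
    stop(sprintf("'tau' must be in [0, %d]", length(policy)), call. = FALSE)
  }
  b <- belief
  for (k in seq_len(tau)) b <- as.numeric(task$B[[policy[k]]] %*% b)
  b
}

#' Posterior predictive outcome distribution
#'
#' @param state_dist distribution over hidden states.
#' @param task a `maze_task`.
#' @return distribution over outcomes, `A %*% state_dist`.
#' @export
outcome_prediction <- function(state_dist, task) {
  as.numeric(task$A %*% state_dist)
}

#' Extrinsic value of a predicted outcome distribution
#'
#' Expected log prior preference (expected utility up to the softmax
#' normaliser) of the outcomes predicted at one future step:
#' `sum_o Q(o) ln P(o | m)`. Always nonpositive, since log preferences are
#' log probabilities.
#'
#' @param outcome_dist distribution over outcomes.
#' @param prefs a [normalize_preferences()] object, or a `maze_task` (whose
#'   preferences are used).
#' @return scalar extrinsic value.
#' @export
extrinsic_value <- function(outcome_dist, prefs) {
  logC <- if (inherits(prefs, "maze_task")) prefs$logC else prefs$log_preferences
  sum(outcome_dist * logC)
}

#' Epistemic value of a predicted state distribution
#'
#' Expected information gain about hidden states under predicted outcomes:
#' `E_{Q(o)}[ KL( Q(s | o) || Q(s) ) ]`, which equals the mutual information
#' between states and outcomes under the joint `P(o | s) Q(s)`. Nonnegative;
#' zero for point-mass beliefs and for uninformative likelihoods.
#'
#' @param state_dist distribution over hidden states.
#' @param task a `maze_task` (its likelihood `A` is used).
#' @return scalar epistemic value (nats).
#' @export
epistemic_value <- function(state_dist, task) {
  A <- if (inherits(task, "maze_task")) task$A else task
  joint <- A * rep(state_dist, each = nrow(A))
  po <- rowSums(joint)
  val <- sum(xlogx(joint)) - sum(xlogx(po)) - sum(xlogx(state_dist))
  max(val, 0) # clip numeric noise at the theoretical floor
}

#' Expected free energy of one policy
#'
#' Scores a policy from the current belief by propagating predictions over the
#' remaining steps and accumulating, at each future step tau, extrinsic value
#' (expected log preference of predicted outcomes) plus epistemic value
#' (expected information gain): the quality `Q(pi) = sum_tau Q_tau(pi)`.
#'
#' @param belief current belief vector.
#' @param policy integer vector of control indices (a row of the task's policy
#'   set).
#' @param task a `maze_task`.
#' @param from_step first step of the policy still to execute (1 scores the
#'   whole policy; within a trial, re-evaluation uses the current step).
#' @return a list of class `"policy_evaluation"` with `per_tau_quality`,
#'   `extrinsic_component`, `epistemic_component` (one entry per remaining
#'   step) and `total_quality`.
#' @export
policy_quality <- function(belief, policy, task, from_step = 1L) {
  steps <- seq(from_step, length(policy))
  ext <- epi <- numeric(length(steps))
  b <- belief
  for (i in seq_along(steps)) {
    b <- as.numeric(task$B[[policy[steps[i]]]] %*% b)
    ext[i] <- extrinsic_value(outcome_prediction(b, task), task)
    epi[i] <- epistemic_value(b, task)
  }
  structure(list(per_tau_quality = ext + epi,
                 extrinsic_component = ext,
                 epistemic_component = epi,
                 total_quality = sum(ext) + sum(epi)),
            class = "policy_evaluation")
}

#' Evaluate all policies of a task
#'
#' Vectorised scoring of the whole policy set from a common belief (policies
#' sharing a control at a given step share the propagation work). Numerically
#' identical to calling [policy_quality()] per policy.
#'
#' @param belief current belief vector.
#' @param task a `maze_task`.
#' @param from_step first step still to execute.
#' @return a list with `total` (vector over policies), `extrinsic` and
#'   `epistemic` (policies x remaining-steps matrices).
#' @export
evaluate_policies <- function(belief, task, from_step = 1L) {
  pol <- task$policies
  n_pol <- nrow(pol)
  steps <- seq(from_step, ncol(pol))
  S <- matrix(belief, nrow = task$n_states, ncol = n_pol)
  ext <- epi <- matrix(0, n_pol, length(steps))
  logC <- task$logC
  A <- task$A
  AtC <- as.numeric(crossprod(A, logC)) # per-state expected log preference
  for (i in seq_along(steps)) {
    u_step <- pol[, steps[i]]
    for (u in unique(u_step)) {
      idx <- which(u_step == u)
      S[, idx] <- task$B[[u]] %*% S[, idx, drop = FALSE]
    }
    ext[, i] <- as.numeric(crossprod(S, AtC))
    epi[, i] <- epistemic_value_all(S, task)
  }
  list(total = rowSums(ext) + rowSums(epi), extrinsic = ext, epistemic = epi)
}

# mutual-information epistemic value for every column of a state-distribution
# matrix at once, exploiting the sparsity of the likelihood
epistemic_value_all <- function(S, task) {
  W <- task$A_val * S[task$A_j, , drop = FALSE] # joint over (outcome, state)
  Hj <- colSums(W * log(pmax(W, .PROB_FLOOR)))  # 0 log 0 = 0 exactly
  PO <- rowsum(W, task$A_i)
  Hpo <- colSums(PO * log(pmax(PO, .PROB_FLOOR)))
  Hq <- colSums(S * log(pmax(S, .PROB_FLOOR)))
  pmax(Hj - Hpo - Hq, 0)
}

#' Policy posterior (precision-weighted softmax)
#'
#' `P(pi) \propto exp(gamma * Q(pi))`: uniform at `gamma = 0`, concentrating
#' on the best policy as `gamma` grows.
#'
#' @param qualities numeric vector of policy qualities `Q(pi)`.
#' @param gamma policy precision (>= 0).
#' @return distribution over policies.
#' @export
policy_posterior <- function(qualities, gamma) {
  if (any(!is.finite(qualities))) stop("non-finite policy quality", call. = FALSE)
  if (gamma < 0) stop("'gamma' must be >= 0", call. = FALSE)
  w <- gamma * qualities
  w <- exp(w - max(w))
  w / sum(w)
}

#' Feasible controls at a location
#'
#' In an absorbing arm only the matching arm control can be selected; anywhere
#' else all controls are available.
#'
#' @param task a `maze_task`.
#' @param location current (generative) location index.
#' @return integer vector of control indices.
#' @export
feasible_controls <- function(task, location) {
  phys <- task$physical[location]
  if (phys %in% task$absorbing_locations) phys else seq_len(task$n_controls)
}

#' Sample the next action from the policy posterior
#'
#' Marginalises the policy posterior onto the control prescribed at the current
#' step, restricts to feasible controls, renormalises and samples
#' (`Pr(a_t = u) = Q(u_t | pi)`).
#'
#' @param policy_post distribution over policies.
#' @param policies the task's `policy_set` (integer matrix).
#' @param step within-trial step index.
#' @param feasible integer vector of selectable controls.
#' @return a sampled control index.
#' @export
select_action <- function(policy_post, policies, step, feasible) {
  u_step <- policies[, step]
  marg <- rowsum(policy_post, u_step)
  probs <- numeric(max(c(feasible, u_step)))
  probs[as.integer(rownames(marg))] <- marg
  probs <- probs[feasible]
  if (sum(probs) <= .PROB_FLOOR) {
    stop("all feasible controls have zero posterior mass", call. = FALSE)
  }
  feasible[sample.int(length(feasible), 1L, prob = probs)]
}

#' One-step variational free energy
#'
#' The free energy of a candidate posterior `q` over hidden states, given the
#' previous belief, the executed control and the observed outcome:
#' `F(q) = E_q[ln q(s') - ln(P(o | s') sum_s P(s' | s, u) prior(s))]`.
#' `F` upper-bounds the negative log evidence `-ln P(o)`, with equality
#' exactly at the Bayesian posterior returned by [bayes_update()] — which is
#' why the package can use exact filtering as the variational fixed point.
#'
#' @param q candidate posterior over hidden states.
#' @param prior belief before the step.
#' @param action executed control index (or `NULL`).
#' @param observation observed outcome index.
#' @param task a `maze_task`.
#' @return scalar free energy (nats).
#' @export
free_energy <- function(q, prior, action, observation, task) {
  stopifnot_prob(q, "q")
  pred <- if (is.null(action)) prior else as.numeric(task$B[[action]] %*% prior)
  joint <- task$A[observation, ] * pred
  sum(xlogx(q)) - sum(ifelse(q > 0, q * log(pmax(joint, .PROB_FLOOR)), 0))
}
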