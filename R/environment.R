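# The generative process: the true state of the maze.
#
# The environment shares the task's contingencies (the agent is assumed to
# know them) but holds the *true* context, which the agent never observes
# directly — only through sampled cues. Transitions are deterministic given
# the action; all stochasticity is in outcome sampling. Covert (imaginary)
# moves update the generative location used for cue sampling but leave the
# animal physically at the decision point.

#' Initialise the environment
#'
#' @param task a `maze_task`.
#' @param context true context index (defaults to the task's initial context).
#' @return an `env_state`: list with `context`, `location` (generative,
#'   possibly imaginary), `physical` (always a real location), `trial`, `step`.
#' @export
init_env <- function(task, context = task$initial_context) {
  structure(list(context = as.integer(context), location = 1L,
                 physical = 1L, trial = 1L, step = 0L),
            class = "env_state")
}

#' Advance the environment by one action
#'
#' Real controls move the animal according to the transition model (respecting
#' absorbing arms and, in the double T-maze, context-dependent barriers);
#' imaginary controls leave the physical location unchanged and mark a sweep
#' event.
#'
#' @param env an `env_state`.
#' @param action control index.
#' @param task a `maze_task`.
#' @return the updated `env_state`, with attributes `sweep` (logical) and
#'   `sweep_tag` (`"easy"`/`"costly"`/`NA`).
#' @export
env_step <- function(env, action, task) {
  s <- state_index(env$location, env$context, task)
  s2 <- which(task$B[[action]][, s] > 0)[1L]
  loc <- state_location(s2, task)
  env$location <- loc
  env$physical <- task$physical[loc]
  env$step <- env$step + 1L
  sweep <- task$location_type[loc] == "imaginary"
  attr(env, "sweep") <- sweep
  attr(env, "sweep_tag") <- if (sweep) task$sweep_tag[loc] else NA_character_
  env
}

#' Sample an outcome at the current environment state
#'
#' Draws an outcome from the likelihood column of the true (location, context)
#' state: the reward cue at the baited arm with probability
#' `reward_reliability`, the context-congruent mnemonic cue at imaginary
#' locations with probability `context_cue_reliability`, the neutral cue
#' elsewhere.
#'
#' @param env an `env_state`.
#' @param task a `maze_task`.
#' @return an outcome index.
#' @export
sample_outcome <- function(env, task) {
  col <- task$A[, state_index(env$location, env$context, task)]
  sample.int(task$n_outcomes, 1L, prob = col)
}

#' Between-trial carryover of the context belief
#'
#' The agent's volatility prior: with probability `volatility` the context
#' switches to one of the other `K - 1` contexts (uniformly), so the next
#' trial's prior is
#' `prior(c) = (1 - v) posterior(c) + v / (K - 1) * sum_{c' != c} posterior(c')`.
#'
#' @param context_posterior end-of-trial distribution over contexts.
#' @param volatility per-trial context-change probability in `[0, 1]`.
#' @return the next trial's context prior.
#' @export
carryover_prior <- function(context_posterior, volatility) {
  stopifnot_prob(context_posterior, "context_posterior")
  if (volatility < 0 || volatility > 1) {
    stop("'volatility' must be in [0, 1]", call. = FALSE)
  }
  K <- length(context_posterior)
  if (K == 1L) return(context_posterior)
  (1 - volatility) * context_posterior +
    volatility * (1 - context_posterior) / (K - 1)
}

#' True context at a given trial
#'
#' @param schedule data.frame with columns `trial`, `context` (strictly
#'   increasing change trials).
#' @param trial trial index.
#' @param initial_context context before the first change.
#' @return the context index in force at `trial`.
#' @export
context_at <- function(schedule, trial, initial_context = 1L) {
  ctx <- as.integer(initial_context)
  if (!is.null(schedule) && nrow(schedule)) {
    if (is.unsorted(schedule$trial, strictly = TRUE)) {
      stop("schedule change trials must be strictly increasing", call. = FALSE)
    }
    hit <- schedule$trial <= trial
    if (any(hit)) ctx <- as.integer(schedule$context[max(which(hit))])
  }
  ctx
}

#' Apply the context schedule and start a new trial
#'
#' Updates the true context if `trial` is at or past a change point and resets
#' the animal to the center/home location. The agent is never informed
#' directly.
#'
#' @param schedule context-change schedule (see [context_at()]).
#' @param trial trial index.
#' @param env an `env_state`.
#' @param initial_context context before the first change.
#' @return the updated `env_state`.
#' @export
advance_context <- function(schedule, trial, env, initial_context = 1L) {
  env$context <- context_at(schedule, trial, initial_context)
  env$trial <- as.integer(trial)
  env$step <- 0L
  env$location <- 1L
  env$physical <- 1L
  env
}
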