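# Generative-model container and validation.
#
# A maze task couples a discrete POMDP generative model to a policy set:
#   hidden states  = locations x contexts   (index = loc + n_loc * (ctx - 1))
#   outcomes       = locations x cues       (index = loc + n_loc * (cue - 1))
#   control states = one per location ("move to location u"; moves to
#                    imaginary locations are covert sweeps)
# The likelihood A gives P(outcome | state) and is deterministic in the
# location component; the per-control transitions B are deterministic in this
# model family (all stochasticity lives in the cues).

#' Agent parameters
#'
#' Bundles the free parameters of the active-inference agent. The cue
#' reliabilities are fixed by the task descriptions (0.75 for the reward cue,
#' 0.85 for contextual cues); precision, volatility and the sweep cost are
#' calibrated per-experiment defaults that can be overridden. The constructor
#' defaults are those of the single-decision-point T-maze experiments; the
#' double T-maze and the reward-grid variant install sharper precision (see
#' [build_double_tmaze()], [sweep_reward_grid()] and the package vignette).
#'
#' @param gamma policy precision (inverse temperature, dimensionless, >= 0).
#' @param volatility agent's prior per-trial probability in `[0, 1]` that the
#'   context changes between trials.
#' @param reward_reliability probability that the baited arm emits the reward
#'   cue.
#' @param context_cue_reliability probability that an imaginary location emits
#'   the context-congruent cue.
#' @param imaginary_cost utility (usually negative) of any outcome observed at
#'   an imaginary location: the cost of a forward sweep.
#' @return an object of class `"agent_params"`.
#' @export
agent_params <- function(gamma = 4,
                         volatility = 0.1,
                         reward_reliability = 0.75,
                         context_cue_reliability = 0.85,
                         imaginary_cost = -0.1) {
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) || gamma < 0) {
    stop("'gamma' must be a single finite number >= 0", call. = FALSE)
  }
  for (nm in c("volatility", "reward_reliability", "context_cue_reliability")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("'%s' must be a single probability in [0, 1]", nm), call. = FALSE)
    }
  }
  if (!is.numeric(imaginary_cost) || length(imaginary_cost) != 1 ||
      !is.finite(imaginary_cost)) {
    stop("'imaginary_cost' must be a single finite number", call. = FALSE)
  }
  structure(list(gamma = gamma, volatility = volatility,
                 reward_reliability = reward_reliability,
                 context_cue_reliability = context_cue_reliability,
                 imaginary_cost = imaginary_cost),
            class = "agent_params")
}

#' Hidden-state index of a (location, context) pair
#' @param location,context integer indices (1-based).
#' @param task a `maze_task`.
#' @export
state_index <- function(location, context, task) {
  location + task$n_locations * (context - 1L)
}

#' Outcome index of a (location, cue) pair
#' @param location,cue integer indices (1-based).
#' @param task a `maze_task`.
#' @export
outcome_index <- function(location, cue, task) {
  location + task$n_locations * (cue - 1L)
}

# location / context components of a state index
state_location <- function(state, task) ((state - 1L) %% task$n_locations) + 1L
state_context <- function(state, task) ((state - 1L) %/% task$n_locations) + 1L
outcome_location <- function(outcome, task) ((outcome - 1L) %% task$n_locations) + 1L
outcome_cue <- function(outcome, task) ((outcome - 1L) %/% task$n_locations) + 1L

# internal constructor shared by the four task builders
new_maze_task <- function(name, locations, location_type, physical, contexts,
                          cues, reward_cues, A, B, utilities,
                          absorbing_locations, horizon, policies,
                          sweep_tag, params, n_trials, schedule,
                          initial_context = 1L) {
  n_loc <- length(locations)
  prefs <- normalize_preferences(utilities)
  task <- structure(list(
    name = name,
    locations = locations,
    location_type = location_type,
    physical = physical,
    contexts = contexts,
    cues = cues,
    reward_cues = reward_cues,
    n_locations = n_loc,
    n_contexts = length(contexts),
    n_cues = length(cues),
    n_states = n_loc * length(contexts),
    n_outcomes = n_loc * length(cues),
    n_controls = n_loc,
    A = A,
    B = B,
    utilities = utilities,
    prefs = prefs,
    logC = prefs$log_preferences,
    absorbing_locations = absorbing_locations,
    horizon = horizon,
    policies = policies,
    imaginary_controls = which(location_type == "imaginary"),
    sweep_tag = sweep_tag,
    params = params,
    n_trials = n_trials,
    schedule = schedule,
    initial_context = initial_context
  ), class = "maze_task")
  # triplet view of the sparse likelihood (each state emits at most a couple
  # of distinct cues) used by the vectorised epistemic-value computation
  nz <- which(A > 0, arr.ind = TRUE)
  task$A_i <- nz[, 1L]
  task$A_j <- nz[, 2L]
  task$A_val <- A[nz]
  task
}

#' @export
print.maze_task <- function(x, ...) {
  cat(sprintf("Maze task '%s': %d hidden states (%d locations x %d contexts), %d outcomes (%d cues), %d control states, %d policies of length %d\n",
              x$name, x$n_states, x$n_locations, x$n_contexts,
              x$n_outcomes, x$n_cues, x$n_controls, nrow(x$policies), x$horizon))
  invisible(x)
}

#' Validate a generative model
#'
#' Checks every structural invariant of a task's generative model and returns
#' a report of violations rather than stopping at the first: likelihood and
#' transition columns must be probability distributions, outcomes must be
#' deterministic in their location component, absorbing states must
#' self-transition with probability one, and no control may change the context
#' component of a hidden state within a trial.
#'
#' @param task a `maze_task` (or a list with the same `A`/`B`/layout fields).
#' @param tol numeric tolerance on column sums.
#' @return a data.frame with columns `component`, `index`, `message`; zero rows
#'   if and only if the model is well formed.
#' @export
validate_model <- function(task, tol = 1e-9) {
  bad <- list()
  note <- function(component, index, message) {
    bad[[length(bad) + 1L]] <<- data.frame(component = component,
                                           index = index,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  A <- task$A
  for (s in seq_len(ncol(A))) {
    col <- A[, s]
    if (any(col < -tol) || abs(sum(col) - 1) > tol) {
      note("likelihood", s, sprintf("column %d of A is not a distribution (sum = %.10g)",
                                    s, sum(col)))
    }
    loc <- state_location(s, task)
    off <- which(col > tol & outcome_location(seq_along(col), task) != loc)
    if (length(off)) {
      note("likelihood", s,
           sprintf("state %d leaks probability to outcomes of another location", s))
    }
  }
  abs_states <- unlist(lapply(task$absorbing_locations, function(l) {
    state_index(l, seq_len(task$n_contexts), task)
  }))
  for (u in seq_along(task$B)) {
    Bu <- task$B[[u]]
    sums <- colSums(Bu)
    badcol <- which(abs(sums - 1) > tol | apply(Bu, 2, min) < -tol)
    for (s in badcol) {
      note("transition", s,
           sprintf("column %d of B[[%d]] is not a distribution (sum = %.10g)", s, u, sums[s]))
    }
    for (s in abs_states) {
      if (abs(Bu[s, s] - 1) > tol) {
        note("absorbing", s,
             sprintf("absorbing state %d leaks under control %d (self-transition %.10g)",
                     s, u, Bu[s, s]))
      }
    }
    # context preservation
    for (s in seq_len(ncol(Bu))) {
      dest <- which(Bu[, s] > tol)
      if (any(state_context(dest, task) != state_context(s, task))) {
        note("context", s,
             sprintf("control %d changes the context component of state %d", u, s))
      }
    }
  }
  if (length(bad)) do.call(rbind, bad) else {
    data.frame(component = character(), index = integer(), message = character(),
               stringsAsFactors = FALSE)
  }
}
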