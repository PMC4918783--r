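# The four built-in maze tasks.
#
# Each builder assembles a validated generative model (likelihood A over
# location x cue outcomes, deterministic per-control transitions B, softmax
# preferences over outcome utilities) together with the task's policy set and
# default trial schedule. Conventions shared by all tasks:
#   * location 1 is the center/home location and emits the neutral cue;
#   * real arms are absorbing: once entered, every control maps back to them;
#   * imaginary locations are covert: "visiting" one emits a mnemonic
#     contextual cue at a small utility cost and does not move the animal;
#   * the reward cue is emitted at the baited arm with probability
#     `reward_reliability` (otherwise the neutral cue); the context-congruent
#     mnemonic cue is emitted with probability `context_cue_reliability`.

build_A <- function(n_loc, n_ctx, n_cues, cue_probs) {
  A <- matrix(0, n_loc * n_cues, n_loc * n_ctx)
  for (ctx in seq_len(n_ctx)) {
    for (loc in seq_len(n_loc)) {
      p <- cue_probs(loc, ctx)
      A[loc + n_loc * (seq_len(n_cues) - 1L), loc + n_loc * (ctx - 1L)] <- p
    }
  }
  A
}

build_B <- function(n_loc, n_ctx, dest) {
  lapply(seq_len(n_loc), function(u) {
    B <- matrix(0, n_loc * n_ctx, n_loc * n_ctx)
    for (ctx in seq_len(n_ctx)) {
      for (loc in seq_len(n_loc)) {
        d <- dest(loc, ctx, u)
        B[d + n_loc * (ctx - 1L), loc + n_loc * (ctx - 1L)] <- 1
      }
    }
    B
  })
}

#' Two-arm T-maze task
#'
#' The basic deliberation task: a T-maze whose left or right arm is baited
#' depending on a hidden context. 5 locations (center, left, right and two
#' imaginary arm locations) x 2 contexts = 10 hidden states; 4 cues (red =
#' reward, white = neutral, blue/green = mnemonic contextual cues) give 20
#' outcomes; 14 policies of length 3 (direct, one-sweep and two-sweep). The
#' context reverses at trial 11 of the 20-trial default schedule.
#'
#' @param params an [agent_params()] object.
#' @return a validated `maze_task`.
#' @export
build_two_arm_tmaze <- function(params = agent_params()) {
  rr <- params$reward_reliability
  cr <- params$context_cue_reliability
  locations <- c("center", "left", "right", "imag_left", "imag_right")
  cues <- c("red", "white", "blue", "green")
  cue_probs <- function(loc, ctx) {
    p <- numeric(4)
    if (loc == 1) p[2] <- 1
    if (loc == 2) { if (ctx == 1) { p[1] <- rr; p[2] <- 1 - rr } else p[2] <- 1 }
    if (loc == 3) { if (ctx == 2) { p[1] <- rr; p[2] <- 1 - rr } else p[2] <- 1 }
    if (loc == 4) { if (ctx == 1) { p[3] <- cr; p[4] <- 1 - cr } else { p[4] <- cr; p[3] <- 1 - cr } }
    if (loc == 5) { if (ctx == 2) { p[3] <- cr; p[4] <- 1 - cr } else { p[4] <- cr; p[3] <- 1 - cr } }
    p
  }
  dest <- function(loc, ctx, u) if (loc %in% c(2L, 3L)) loc else u
  utilities <- numeric(20)
  n_loc <- 5L
  utilities[outcome_index_raw(c(2, 3), 1, n_loc)] <- 2     # arm + reward cue
  utilities[outcome_index_raw(c(2, 3), 2, n_loc)] <- -2    # arm + neutral cue
  for (cue in 1:4) utilities[outcome_index_raw(c(4, 5), cue, n_loc)] <- params$imaginary_cost
  new_maze_task(
    name = "sim1",
    locations = locations,
    location_type = c("real", "real", "real", "imaginary", "imaginary"),
    physical = c(1L, 2L, 3L, 1L, 1L),
    contexts = c("left", "right"),
    cues = cues, reward_cues = 1L,
    A = build_A(5L, 2L, 4L, cue_probs),
    B = build_B(5L, 2L, dest),
    utilities = utilities,
    absorbing_locations = c(2L, 3L),
    horizon = 3L,
    policies = enumerate_policies("sim1"),
    sweep_tag = c(NA, NA, NA, "costly", "costly"),
    params = params,
    n_trials = 20L,
    schedule = data.frame(trial = 11L, context = 2L)
  )
}

#' Three-arm radial maze task
#'
#' Radial maze with three arms and three mutually exclusive reward contexts:
#' 7 locations x 3 contexts = 21 hidden states, 28 outcomes, 48 policies of
#' length 4 (up to three distinct ordered sweeps before committing to an arm).
#' Contexts change at trials 11 and 21 of the 30-trial default schedule.
#'
#' @param params an [agent_params()] object.
#' @return a validated `maze_task`.
#' @export
build_three_arm_radial <- function(params = agent_params()) {
  rr <- params$reward_reliability
  cr <- params$context_cue_reliability
  locations <- c("center", "arm_left", "arm_center", "arm_right",
                 "imag_left", "imag_center", "imag_right")
  cue_probs <- function(loc, ctx) {
    p <- numeric(4)
    if (loc == 1) p[2] <- 1
    if (loc %in% 2:4) {
      if (ctx == loc - 1L) { p[1] <- rr; p[2] <- 1 - rr } else p[2] <- 1
    }
    if (loc %in% 5:7) {
      if (ctx == loc - 4L) { p[3] <- cr; p[4] <- 1 - cr } else { p[4] <- cr; p[3] <- 1 - cr }
    }
    p
  }
  dest <- function(loc, ctx, u) if (loc %in% 2:4) loc else u
  utilities <- numeric(28)
  utilities[outcome_index_raw(2:4, 1, 7L)] <- 2
  utilities[outcome_index_raw(2:4, 2, 7L)] <- -2
  for (cue in 1:4) utilities[outcome_index_raw(5:7, cue, 7L)] <- params$imaginary_cost
  new_maze_task(
    name = "sim2",
    locations = locations,
    location_type = c("real", "real", "real", "real",
                      "imaginary", "imaginary", "imaginary"),
    physical = c(1L, 2L, 3L, 4L, 1L, 1L, 1L),
    contexts = c("left", "center", "right"),
    cues = c("red", "white", "blue", "green"), reward_cues = 1L,
    A = build_A(7L, 3L, 4L, cue_probs),
    B = build_B(7L, 3L, dest),
    utilities = utilities,
    absorbing_locations = 2:4,
    horizon = 4L,
    policies = enumerate_policies("sim2"),
    sweep_tag = c(NA, NA, NA, NA, "costly", "costly", "costly"),
    params = params,
    n_trials = 30L,
    schedule = data.frame(trial = c(11L, 21L), context = c(2L, 3L))
  )
}

#' Double T-maze task (easy versus costly choice)
#'
#' Two consecutive decision points. The first ("easy") choice selects one of
#' two costly decision points; a context-dependent barrier blocks the
#' unreachable side, so a wrong easy choice fails observably (the animal stays
#' put) and can be undone. The second ("costly") choice enters an absorbing
#' final arm. 11 locations (home, two costly decision points, two shared final
#' arms, two easy-point and four costly-point imaginary locations) x 4 contexts
#' (left-left, left-right, right-left, right-right) = 44 hidden states; 11
#' control states; 6 cues (red, white, blue, green, yellow, black). Easy-point
#' sweeps retrieve the yellow/black cue that signals the open side (partition
#' {LL, LR} vs {RL, RR}); costly-point sweeps retrieve blue/green reward
#' recall exactly as in the simpler mazes. Contexts follow LL, LR, RL, RR in
#' blocks of 10 trials over the 40-trial default schedule.
#'
#' In this task a wrong costly choice is punishing precisely because it wastes
#' time, so transit locations (home and the two costly decision points) carry
#' a small time cost per step (`transit_cost`): loitering is strictly worse
#' than acting, and covert sweeps (cheaper than transit) remain the preferred
#' way to spend a step when the context is uncertain.
#'
#' @param params an [agent_params()] object; the default uses sharper policy
#'   precision and a slightly larger sweep cost than the single-decision-point
#'   tasks (calibration discussed in the vignette).
#' @param transit_cost utility of spending a step at a non-goal real location.
#' @return a validated `maze_task`.
#' @export
build_double_tmaze <- function(params = agent_params(gamma = 7,
                                                     imaginary_cost = -0.15),
                               transit_cost = -0.5) {
  rr <- params$reward_reliability
  cr <- params$context_cue_reliability
  locations <- c("home", "dp_left", "dp_right", "final_left", "final_right",
                 "imag_easy_left", "imag_easy_right",
                 "imag_dpL_left", "imag_dpL_right",
                 "imag_dpR_left", "imag_dpR_right")
  # contexts: 1 = LL, 2 = LR, 3 = RL, 4 = RR
  left_open <- function(ctx) ctx %in% c(1L, 2L)
  final_left_rewarded <- function(ctx) ctx %in% c(1L, 3L)
  cue_probs <- function(loc, ctx) {
    p <- numeric(6)
    if (loc %in% 1:3) p[2] <- 1
    if (loc == 4) {
      if (final_left_rewarded(ctx)) { p[1] <- rr; p[2] <- 1 - rr } else p[2] <- 1
    }
    if (loc == 5) {
      if (!final_left_rewarded(ctx)) { p[1] <- rr; p[2] <- 1 - rr } else p[2] <- 1
    }
    if (loc %in% 6:7) {
      if (left_open(ctx)) { p[5] <- cr; p[6] <- 1 - cr } else { p[6] <- cr; p[5] <- 1 - cr }
    }
    if (loc %in% c(8L, 10L)) {
      if (final_left_rewarded(ctx)) { p[3] <- cr; p[4] <- 1 - cr } else { p[4] <- cr; p[3] <- 1 - cr }
    }
    if (loc %in% c(9L, 11L)) {
      if (!final_left_rewarded(ctx)) { p[3] <- cr; p[4] <- 1 - cr } else { p[4] <- cr; p[3] <- 1 - cr }
    }
    p
  }
  physical <- c(1L, 2L, 3L, 4L, 5L, 1L, 1L, 2L, 2L, 3L, 3L)
  dest <- function(loc, ctx, u) {
    if (loc %in% c(4L, 5L)) return(loc)          # final arms absorb
    p <- physical[loc]
    allowed <- switch(p,
      c(1L, 6L, 7L, if (left_open(ctx)) 2L else 3L),   # home (barrier)
      c(2L, 4L, 5L, 8L, 9L, 1L),                       # left costly DP
      c(3L, 4L, 5L, 10L, 11L, 1L))                     # right costly DP
    if (u %in% allowed) u else p                       # blocked move: stay put
  }
  utilities <- numeric(66)
  utilities[outcome_index_raw(c(4, 5), 1, 11L)] <- 2
  utilities[outcome_index_raw(c(4, 5), 2, 11L)] <- -2
  utilities[outcome_index_raw(1:3, 2, 11L)] <- transit_cost
  for (cue in 1:6) utilities[outcome_index_raw(6:11, cue, 11L)] <- params$imaginary_cost
  new_maze_task(
    name = "sim3",
    locations = locations,
    location_type = c(rep("real", 5), rep("imaginary", 6)),
    physical = physical,
    contexts = c("left_left", "left_right", "right_left", "right_right"),
    cues = c("red", "white", "blue", "green", "yellow", "black"),
    reward_cues = 1L,
    A = build_A(11L, 4L, 6L, cue_probs),
    B = build_B(11L, 4L, dest),
    utilities = utilities,
    absorbing_locations = c(4L, 5L),
    horizon = 4L,
    policies = enumerate_policies("sim3"),
    sweep_tag = c(rep(NA, 5), "easy", "easy", rep("costly", 4)),
    params = params,
    n_trials = 40L,
    schedule = data.frame(trial = c(11L, 21L, 31L), context = c(2L, 3L, 4L))
  )
}

#' Plentiful-reward T-maze task
#'
#' The two-arm T-maze with four contexts: contexts 1-2 reproduce the basic
#' task (one baited arm, utilities +2 / -2); contexts 3-4 bait both arms, one
#' with the "usual" reward and the other with a "high" reward
#' (`usual_reward + diff`; by default the high reward is twice the usual one).
#' Two extra cues (dark red, dark blue) signal the presence and the episodic
#' retrieval of the high reward. 5 locations x 4 contexts = 20 hidden states,
#' 30 outcomes, the same 5 control states and 14 policies as the basic task.
#' The default 40-trial schedule switches context at trials 10, 20 and 30.
#'
#' @param params an [agent_params()] object.
#' @param usual_reward utility of the usual reward (the red cue).
#' @param diff nonnegative differential of the high reward over the usual one
#'   (the dark-red cue has utility `usual_reward + diff`).
#' @return a validated `maze_task`.
#' @export
build_plentiful_tmaze <- function(params = agent_params(), usual_reward = 2,
                                  diff = usual_reward) {
  if (!is.numeric(diff) || length(diff) != 1 || !is.finite(diff) || diff < 0) {
    stop("'diff' must be a single nonnegative number", call. = FALSE)
  }
  rr <- params$reward_reliability
  cr <- params$context_cue_reliability
  # contexts: 1 = reward left, 2 = reward right,
  #           3 = usual left / high right, 4 = high left / usual right
  # cues: 1 red, 2 white, 3 blue, 4 green, 5 dark_red, 6 dark_blue
  arm_reward_cue <- function(loc, ctx) {
    # 0 = none, 1 = red (usual), 5 = dark red (high)
    if (loc == 2) switch(ctx, 1L, 0L, 1L, 5L) else switch(ctx, 0L, 1L, 5L, 1L)
  }
  cue_probs <- function(loc, ctx) {
    p <- numeric(6)
    if (loc == 1) p[2] <- 1
    if (loc %in% c(2L, 3L)) {
      rc <- arm_reward_cue(loc, ctx)
      if (rc == 0) p[2] <- 1 else { p[rc] <- rr; p[2] <- 1 - rr }
    }
    if (loc %in% c(4L, 5L)) {
      rc <- arm_reward_cue(loc - 2L, ctx)        # recall of the matching arm
      mc <- if (rc == 0) 4L else if (rc == 1L) 3L else 6L  # green / blue / dark blue
      p[mc] <- cr
      alt <- if (mc == 4L) 3L else 4L            # failed retrieval: other recall
      p[alt] <- 1 - cr
    }
    p
  }
  dest <- function(loc, ctx, u) if (loc %in% c(2L, 3L)) loc else u
  utilities <- numeric(30)
  utilities[outcome_index_raw(c(2, 3), 1, 5L)] <- usual_reward
  utilities[outcome_index_raw(c(2, 3), 5, 5L)] <- usual_reward + diff
  utilities[outcome_index_raw(c(2, 3), 2, 5L)] <- -2
  for (cue in 1:6) utilities[outcome_index_raw(c(4, 5), cue, 5L)] <- params$imaginary_cost
  new_maze_task(
    name = "sim4",
    locations = c("center", "left", "right", "imag_left", "imag_right"),
    location_type = c("real", "real", "real", "imaginary", "imaginary"),
    physical = c(1L, 2L, 3L, 1L, 1L),
    contexts = c("left", "right", "usualL_highR", "highL_usualR"),
    cues = c("red", "white", "blue", "green", "dark_red", "dark_blue"),
    reward_cues = c(1L, 5L),
    A = build_A(5L, 4L, 6L, cue_probs),
    B = build_B(5L, 4L, dest),
    utilities = utilities,
    absorbing_locations = c(2L, 3L),
    horizon = 3L,
    policies = enumerate_policies("sim4"),
    sweep_tag = c(NA, NA, NA, "costly", "costly"),
    params = params,
    n_trials = 40L,
    schedule = data.frame(trial = c(10L, 20L, 30L), context = c(2L, 3L, 4L))
  )
}

# raw outcome index (before a task object exists)
outcome_index_raw <- function(location, cue, n_loc) {
  as.integer(outer(location, cue, function(l, c) l + n_loc * (c - 1L)))
}

#' Build a task by name
#'
#' @param name one of `"sim1"`, `"sim2"`, `"sim3"`, `"sim4"`.
#' @param params an [agent_params()] object, or `NULL` for the task's
#'   calibrated default parameter set.
#' @param ... passed on to the specific builder (e.g. `usual_reward`, `diff`
#'   for `"sim4"`).
#' @return a `maze_task`.
#' @export
build_task <- function(name, params = NULL, ...) {
  use <- function(f, ...) if (is.null(params)) f(...) else f(params, ...)
  switch(name,
    sim1 = use(build_two_arm_tmaze),
    sim2 = use(build_three_arm_radial),
    sim3 = use(build_double_tmaze),
    sim4 = use(build_plentiful_tmaze, ...),
    stop(sprintf("unknown simulation '%s'", name), call. = FALSE)
  )
}
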