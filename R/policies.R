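# Policy enumeration.
#
# A policy is a fixed-length sequence of control states; sweeps (controls that
# move to imaginary locations) may occupy the leading steps, after which the
# chosen arm control pads the remaining horizon (arm states are absorbing, so
# repeating the arm control is the only continuation).

# Build the policy matrix with its per-step imaginary mask.
as_policy_set <- function(mat, imaginary_controls) {
  mat <- matrix(as.integer(mat), nrow = nrow(mat))
  attr(mat, "imaginary_mask") <- matrix(mat %in% imaginary_controls, nrow = nrow(mat))
  class(mat) <- c("policy_set", class(mat))
  mat
}

#' @export
print.policy_set <- function(x, ...) {
  cat(sprintf("Policy set: %d policies of length %d (%d contain sweeps)\n",
              nrow(x), ncol(x), sum(rowSums(attr(x, "imaginary_mask")) > 0)))
  invisible(x)
}

#' Enumerate sweep-then-arm policies (single decision point)
#'
#' Generates all policies consisting of `k` covert sweeps (`k = 0 ... max_sweeps`)
#' followed by a single arm choice repeated to the end of the horizon. With two
#' arms, two sweeps and repeated sweeps allowed (horizon 3) this yields 14
#' policies; with three arms, three distinct ordered sweeps (horizon 4) it
#' yields 48.
#'
#' @param arms integer control indices of the real arm moves.
#' @param sweeps integer control indices of the covert (imaginary) moves.
#' @param horizon policy length.
#' @param max_sweeps maximum number of leading sweep steps (capped at
#'   `horizon - 1`).
#' @param distinct logical; if `TRUE` a policy may not repeat a sweep.
#' @return a `policy_set`: an integer matrix (one row per policy) carrying an
#'   `imaginary_mask` attribute.
#' @export
enumerate_arm_sweep_policies <- function(arms, sweeps, horizon,
                                         max_sweeps = length(sweeps),
                                         distinct = FALSE) {
  stopifnot(horizon >= 1, length(arms) >= 1)
  max_sweeps <- min(max_sweeps, horizon - 1L, if (distinct) length(sweeps) else Inf)
  rows <- list()
  for (k in 0:max_sweeps) {
    if (k == 0) {
      prefixes <- matrix(integer(0), nrow = 1, ncol = 0)
    } else {
      prefixes <- as.matrix(expand.grid(rep(list(sweeps), k)))[, seq_len(k), drop = FALSE]
      if (distinct && k > 1) {
        keep <- apply(prefixes, 1, function(r) !anyDuplicated(r))
        prefixes <- prefixes[keep, , drop = FALSE]
      }
      # deterministic order: sort rows lexicographically
      ord <- do.call(order, as.data.frame(prefixes))
      prefixes <- prefixes[ord, , drop = FALSE]
    }
    for (i in seq_len(nrow(prefixes))) {
      for (a in arms) {
        rows[[length(rows) + 1L]] <- c(prefixes[i, ], rep(a, horizon - k))
      }
    }
  }
  as_policy_set(do.call(rbind, rows), sweeps)
}

#' Enumerate double T-maze policies (two decision points)
#'
#' Policies combine real moves and at most one sweep per decision point, with
#' unused sweep slots filled by real moves. Five classes: direct
#' (`easy choice, final choice, pad`), easy-sweep
#' (`easy sweep, easy choice, final, pad`), costly-sweep
#' (`easy choice, costly sweep, final, pad`), probe
#' (`one easy choice, the other easy choice, final, pad` — the recovery plan
#' when the first path turns out blocked) and probe-plus-costly-sweep
#' (`easy choice, other easy choice, costly sweep at the reached point,
#' final`). Policies never contain two sweeps, so one-sweep plans are not
#' pitted against two-sweep plans.
#'
#' @param easy_choices integer controls moving to the two costly decision
#'   points.
#' @param final_choices integer controls moving to the two final (absorbing)
#'   arms.
#' @param easy_sweeps integer controls of the easy-point imaginary locations.
#' @param costly_sweeps named list mapping each easy choice (as character
#'   index) to the integer controls of that decision point's imaginary
#'   locations.
#' @param horizon policy length (4).
#' @return a `policy_set`.
#' @export
enumerate_double_tmaze_policies <- function(easy_choices, final_choices,
                                            easy_sweeps, costly_sweeps,
                                            horizon = 4L) {
  all_sweeps <- c(easy_sweeps, unlist(costly_sweeps, use.names = FALSE))
  rows <- list()
  pad <- function(p) c(p, rep(p[length(p)], horizon - length(p)))
  for (e in easy_choices) {
    cs <- costly_sweeps[[as.character(e)]]
    other <- setdiff(easy_choices, e)
    for (f in final_choices) {
      rows[[length(rows) + 1L]] <- pad(c(e, f))
      for (sc in cs) rows[[length(rows) + 1L]] <- pad(c(e, sc, f))
      for (se in easy_sweeps) rows[[length(rows) + 1L]] <- pad(c(se, e, f))
      for (e2 in other) {
        rows[[length(rows) + 1L]] <- pad(c(e, e2, f))
        for (sc2 in costly_sweeps[[as.character(e2)]]) {
          rows[[length(rows) + 1L]] <- pad(c(e, e2, sc2, f))
        }
      }
    }
  }
  as_policy_set(do.call(rbind, rows), all_sweeps)
}

#' Policy set of a built-in task
#'
#' Returns the policy set of a task, addressable either by a built `maze_task`
#' or by its identifier (`"sim1"`, `"sim2"`, `"sim3"`, `"sim4"`).
#'
#' @param task a `maze_task` or a task name.
#' @return a `policy_set`.
#' @export
enumerate_policies <- function(task) {
  if (inherits(task, "maze_task")) return(task$policies)
  if (!is.character(task) || length(task) != 1) {
    stop("'task' must be a maze_task or a task name", call. = FALSE)
  }
  switch(task,
    sim1 = ,
    sim4 = enumerate_arm_sweep_policies(arms = c(2L, 3L), sweeps = c(4L, 5L),
                                        horizon = 3L, max_sweeps = 2L,
                                        distinct = FALSE),
    sim2 = enumerate_arm_sweep_policies(arms = c(2L, 3L, 4L),
                                        sweeps = c(5L, 6L, 7L),
                                        horizon = 4L, max_sweeps = 3L,
                                        distinct = TRUE),
    sim3 = enumerate_double_tmaze_policies(
      easy_choices = c(2L, 3L), final_choices = c(4L, 5L),
      easy_sweeps = c(6L, 7L),
      costly_sweeps = list(`2` = c(8L, 9L), `3` = c(10L, 11L)),
      horizon = 4L),
    stop(sprintf("unknown task identifier '%s'", task), call. = FALSE)
  )
}
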