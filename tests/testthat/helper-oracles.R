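# Independent oracles used across the test files. These deliberately avoid
# the package's vectorised code paths: plain loops and textbook formulas.

# Exact filtering posterior by enumerating the joint over (s, s', o).
brute_force_posterior <- function(belief, action, observation, task) {
  n <- task$n_states
  joint <- numeric(n) # P(s' , o) for the fixed observation
  for (s2 in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) {
      acc <- acc + task$A[observation, s2] * task$B[[action]][s2, s] * belief[s]
    }
    joint[s2] <- acc
  }
  joint / sum(joint)
}

# Epistemic value straight from its definition:
# E_{Q(o)}[ KL( Q(s|o) || Q(s) ) ] with Q(s|o) the Bayes posterior.
kl_form_epistemic <- function(state_dist, A) {
  po <- as.numeric(A %*% state_dist)
  val <- 0
  for (o in which(po > 0)) {
    post <- A[o, ] * state_dist / po[o]
    nz <- post > 0
    val <- val + po[o] * sum(post[nz] * log(post[nz] / state_dist[nz]))
  }
  val
}

# A minimal task-like object with an identity likelihood over n states,
# enough for the engine functions that only touch A / logC / B.
identity_task <- function(n, utilities = rnorm(n)) {
  prefs <- normalize_preferences(utilities)
  structure(list(
    A = diag(n), logC = prefs$log_preferences, prefs = prefs,
    utilities = utilities, n_states = n, n_outcomes = n,
    B = list(diag(n))
  ), class = "maze_task")
}

# textbook KL divergence
kl_div_ref <- function(q, p) {
  nz <- q > 0
  sum(q[nz] * log(q[nz] / p[nz]))
}
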