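# Small numeric helpers shared across the package.

# Probability floor used inside logarithms. Keeps KL/entropy terms finite for
# structurally-zero entries without changing results at reported precision.
.PROB_FLOOR <- 1e-16

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# x * log(x) with the convention 0 * log(0) = 0
xlogx <- function(x) {
  out <- x * log(pmax(x, .PROB_FLOOR))
  out[x <= 0] <- 0
  out
}

# Shannon entropy (nats) of a categorical distribution
shannon_entropy <- function(p) -sum(xlogx(p))

#' Kullback-Leibler divergence between two categorical distributions
#'
#' @param q,p numeric probability vectors of equal length.
#' @return `D(q || p)` in nats.
#' @keywords internal
kl_divergence <- function(q, p) {
  sum(xlogx(q)) - sum(ifelse(q > 0, q * log(pmax(p, .PROB_FLOOR)), 0))
}

is_prob_vector <- function(p, tol = 1e-12) {
  is.numeric(p) && all(is.finite(p)) && all(p >= -tol) && abs(sum(p) - 1) <= tol
}

stopifnot_prob <- function(p, what = "distribution", tol = 1e-9) {
  if (!is_prob_vector(p, tol)) {
    stop(sprintf("'%s' is not a valid probability distribution (sum = %.12g)",
                 what, sum(p)), call. = FALSE)
  }
  invisible(p)
}

# Polynomial rolling hash (mod 2^31 - 1) of a character vector; used to stamp
# output files with a reproducible fingerprint of the configuration.
config_fingerprint <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  m <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 131 + b + 1) %% m
  sprintf("%08x", h)
}
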