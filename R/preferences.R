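#' Prior preferences over outcomes from utilities
#'
#' In active inference, goals are encoded as a prior distribution over
#' outcomes: the log preference of each outcome is its utility, normalised so
#' that the preference distribution sums to one (a softmax over utilities).
#' Only utility *differences* matter; shifting all utilities by a constant
#' leaves the log preferences unchanged.
#'
#' @param utilities numeric vector, one utility (reward magnitude or cost) per
#'   outcome. Positive values are rewards, negative values costs.
#' @return an object of class `"preferences"`: a list with `utilities` and
#'   `log_preferences` (`log_preferences[i] = utilities[i] - log sum exp(utilities)`).
#' @examples
#' p <- normalize_preferences(c(2, -2))
#' sum(exp(p$log_preferences))  # 1
#' @export
normalize_preferences <- function(utilities) {
  if (length(utilities) < 1 || !is.numeric(utilities) || any(!is.finite(utilities))) {
    stop("'utilities' must be a non-empty finite numeric vector", call. = FALSE)
  }
  lp <- utilities - logsumexp(utilities)
  structure(list(utilities = as.numeric(utilities),
                 log_preferences = as.numeric(lp)),
            class = "preferences")
}

#' @export
print.preferences <- function(x, ...) {
  cat("Outcome preferences over", length(x$utilities), "outcomes\n")
  cat("  utility range: [", min(x$utilities), ",", max(x$utilities), "]\n")
  invisible(x)
}
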