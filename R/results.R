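# Result serialisation: tidy CSV + JSON summary, lossless round trip.

#' Tidy per-trial metrics of an experiment result
#'
#' @param result an `experiment_result`.
#' @return a data.frame with columns `simulation`, `trial`, `metric`, `value`,
#'   `n_runs`, `seed` (one row per trial x metric, including the per-context
#'   belief trajectory as `belief_<context>` metrics).
#' @export
tidy_result <- function(result) {
  tr <- result$trials
  metrics <- setdiff(names(tr), "trial")
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(simulation = result$simulation, trial = tr$trial,
               metric = m, value = tr[[m]], stringsAsFactors = FALSE)
  }))
  bel <- do.call(rbind, lapply(colnames(result$belief), function(ctx) {
    data.frame(simulation = result$simulation, trial = seq_len(result$n_trials),
               metric = paste0("belief_", ctx), value = result$belief[, ctx],
               stringsAsFactors = FALSE)
  }))
  out <- rbind(long, bel)
  out$n_runs <- result$n_runs
  out$seed <- result$seed
  out
}

#' Write an experiment result (or reward grid) to CSV and JSON
#'
#' The CSV is tidy (one row per trial x metric, or per grid cell); values are
#' printed with 17 significant digits so the round trip through
#' [read_results()] is lossless at double precision. Both files embed the seed
#' and a fingerprint of the configuration.
#'
#' @param result an `experiment_result`, or a reward-grid data.frame from
#'   [sweep_reward_grid()].
#' @param csv_path output CSV path.
#' @param json_path optional JSON summary path.
#' @param config_hash optional configuration fingerprint to embed (taken from
#'   `result$config_hash` when present).
#' @return invisibly, the data.frame written.
#' @export
write_results <- function(result, csv_path, json_path = NULL,
                          config_hash = NULL) {
  if (inherits(result, "experiment_result")) {
    df <- tidy_result(result)
    hash <- config_hash %||% result$config_hash %||% "unset"
    summary <- list(kind = "experiment", simulation = result$simulation,
                    n_runs = result$n_runs, n_trials = result$n_trials,
                    seed = result$seed, config_hash = hash,
                    mean_performance = mean(result$trials$performance),
                    mean_vte_fraction = mean(result$trials$vte_fraction))
  } else if (is.data.frame(result)) {
    df <- result
    hash <- config_hash %||% "unset"
    summary <- list(kind = "reward_grid", n_cells = nrow(result),
                    n_runs = result$n_runs[1], seed = NA,
                    config_hash = hash)
  } else {
    stop("'result' must be an experiment_result or a data.frame", call. = FALSE)
  }
  df$config_hash <- hash
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(df)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param csv_path path to the CSV.
#' @return the data.frame, with numeric columns restored at full precision.
#' @export
read_results <- function(csv_path) {
  utils::read.csv(csv_path, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
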