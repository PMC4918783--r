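# Experiment configuration: YAML file + programmatic overrides -> validated
# config object.

default_config <- function(simulation = "sim1") {
  p <- if (identical(simulation, "sim3")) {
    agent_params(gamma = 7, imaginary_cost = -0.15)
  } else {
    agent_params()
  }
  list(
    simulation = simulation,
    agent = p[c("gamma", "volatility", "reward_reliability",
                "context_cue_reliability", "imaginary_cost")],
    task = list(usual_reward = 2, diff = 2),
    schedule = NULL,
    runs = list(n_runs = 1000L, seed = 1L, n_trials = NULL)
  )
}

# recursive merge of override values into defaults, rejecting unknown keys
merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base) && !identical(key, "schedule")) {
      stop(sprintf("unknown configuration key '%s'", full), call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !identical(key, "schedule")) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[key] <- override[key]
    }
  }
  base
}

#' Load and validate an experiment configuration
#'
#' Merges (in increasing precedence) built-in defaults, a YAML configuration
#' file with sections `simulation`, `agent`, `task`, `schedule`, `runs`, and a
#' list of literal overrides. Unknown keys and out-of-range probabilities are
#' rejected with descriptive errors.
#'
#' @param path optional path to a YAML file.
#' @param overrides optional named list of overrides (same structure as the
#'   file).
#' @param simulation default simulation name if neither source names one.
#' @return a validated config object of class `"vte_config"`.
#' @export
load_config <- function(path = NULL, overrides = list(), simulation = "sim1") {
  cfg <- default_config(simulation)
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
    file_cfg <- yaml::read_yaml(path)
    if (!is.list(file_cfg)) stop("malformed config file", call. = FALSE)
    cfg <- merge_config(cfg, file_cfg)
  }
  cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!cfg$simulation %in% c("sim1", "sim2", "sim3", "sim4")) {
    stop(sprintf("unknown simulation '%s'", cfg$simulation), call. = FALSE)
  }
  a <- cfg$agent
  params <- agent_params(gamma = a$gamma, volatility = a$volatility,
                         reward_reliability = a$reward_reliability,
                         context_cue_reliability = a$context_cue_reliability,
                         imaginary_cost = a$imaginary_cost)
  if (!is.null(cfg$task$diff) && cfg$task$diff < 0) {
    stop("'task.diff' must be nonnegative", call. = FALSE)
  }
  r <- cfg$runs
  if (!is.numeric(r$n_runs) || r$n_runs < 1) {
    stop("'runs.n_runs' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(r$seed)) stop("'runs.seed' must be an integer", call. = FALSE)
  if (!is.null(cfg$schedule)) {
    cfg$schedule <- as_schedule(cfg$schedule)
  }
  cfg$params <- params
  class(cfg) <- "vte_config"
  cfg
}

# schedule given as a list of {trial:, context:} entries (YAML) or data.frame
as_schedule <- function(x) {
  if (is.data.frame(x)) {
    df <- x
  } else {
    df <- do.call(rbind, lapply(x, function(e) {
      data.frame(trial = as.integer(e$trial), context = as.integer(e$context))
    }))
  }
  if (!all(c("trial", "context") %in% names(df))) {
    stop("schedule entries need 'trial' and 'context'", call. = FALSE)
  }
  if (is.unsorted(df$trial, strictly = TRUE)) {
    stop("schedule change trials must be strictly increasing", call. = FALSE)
  }
  df
}

# fingerprint of a config for provenance stamping
config_hash <- function(cfg) {
  flat <- utils::capture.output(utils::str(cfg[setdiff(names(cfg), "params")],
                                           digits.d = 15))
  config_fingerprint(flat)
}

#' Run the experiment described by a configuration
#'
#' @param cfg a `vte_config` from [load_config()].
#' @return an `experiment_result`.
#' @export
run_config <- function(cfg) {
  stopifnot(inherits(cfg, "vte_config"))
  task_args <- if (cfg$simulation == "sim4") {
    list(usual_reward = cfg$task$usual_reward, diff = cfg$task$diff)
  } else list()
  task <- do.call(build_task, c(list(cfg$simulation, cfg$params), task_args))
  if (!is.null(cfg$schedule)) task$schedule <- cfg$schedule
  if (!is.null(cfg$runs$n_trials)) task$n_trials <- as.integer(cfg$runs$n_trials)
  n_runs <- as.integer(cfg$runs$n_runs)
  seed <- as.integer(cfg$runs$seed)
  records <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    records[[r]] <- run_one(task)
  }
  res <- compute_metrics(records, task, seed = seed)
  res$config_hash <- config_hash(cfg)
  res
}
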