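# Run configuration, serialization and the command dispatcher behind the
# command-line driver (inst/cli/pubcanon.R). Configs are flat YAML documents
# whose keys mirror the CLI flags one-to-one; results go to CSV with a JSON
# sidecar holding the exact parameter snapshot.

PARAM_KEYS <- c("alpha", "alpha_act", "beta", "rho0", "rho1",
                "q0", "tau0", "tau1", "epsilon")
POLICY_KEYS <- c("mode", "rho_b")
EXPERIMENT_KEYS <- c("command", "truth", "grid", "tau0_values", "n_reps",
                     "seed", "level", "counts", "max_k", "max_experiments",
                     "output")
COMMANDS <- c("absorb", "simulate", "sweep-rho0", "sweep-q0", "sweep-tau",
              "roc", "drift", "dynamic", "threshold", "ratio")

#' Assemble and validate a run configuration
#'
#' @param params a [model_params()] object (or a named list of its fields).
#' @param policy a [publication_policy()] object (or list with `mode`,
#'   `rho_b`).
#' @param experiment named list describing what to run: `command` (one of
#'   `absorb`, `simulate`, `sweep-rho0`, `sweep-q0`, `sweep-tau`, `roc`,
#'   `drift`, `dynamic`, `threshold`, `ratio`), and the command's inputs
#'   among `truth`, `grid`, `tau0_values`, `n_reps`, `seed`, `level`,
#'   `counts`, `max_k`, `max_experiments`, `output` (output directory).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(params, policy = publication_policy(),
                       experiment = list(command = "absorb")) {
  if (!inherits(params, "model_params")) {
    bad <- setdiff(names(params), PARAM_KEYS)
    if (length(bad))
      abort_validation(paste0("unknown parameter key(s): ",
                              paste(bad, collapse = ", ")))
    params <- do.call(model_params, params)
  }
  if (!inherits(policy, "publication_policy")) {
    bad <- setdiff(names(policy), POLICY_KEYS)
    if (length(bad))
      abort_validation(paste0("unknown policy key(s): ",
                              paste(bad, collapse = ", ")))
    policy <- publication_policy(policy$mode %||% "constant", policy$rho_b)
  }
  bad <- setdiff(names(experiment), EXPERIMENT_KEYS)
  if (length(bad))
    abort_validation(paste0("unknown experiment key(s): ",
                            paste(bad, collapse = ", ")))
  if (is.null(experiment$command) || !experiment$command %in% COMMANDS)
    abort_validation(paste0("experiment command must be one of: ",
                            paste(COMMANDS, collapse = ", ")))
  if (!is.null(experiment$truth))
    experiment$truth <- truth_value(experiment$truth)
  structure(list(params = params, policy = policy, experiment = experiment),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a run configuration from file and/or overrides
#'
#' Reads a YAML (or JSON) configuration document and applies overrides on
#' top — overrides mirror CLI flags and win over file values. Model-parameter
#' keys sit at the top level; the `policy` and `experiment` blocks are
#' nested. Unknown keys are rejected, and the assembled configuration is
#' fully validated, with defaults (`rho1 = 1`, `epsilon = 1e-4`,
#' `alpha_act = alpha`) applied explicitly and echoed to standard error.
#'
#' @param path path to a YAML/JSON config file, or `NULL` to build from
#'   `overrides` alone.
#' @param overrides named list; names are top-level parameter keys or
#'   dotted paths into the nested blocks (`"policy.rho_b"`,
#'   `"experiment.seed"`).
#' @param quiet suppress the echo of applied defaults.
#' @return A validated `"run_config"`.
#' @export
parse_config <- function(path = NULL, overrides = list(), quiet = FALSE) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path))
      abort_validation(paste0("config file not found: ", path))
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) raw[[parts]] <- overrides[[key]]
    else if (length(parts) == 2L) raw[[parts[1]]][[parts[2]]] <- overrides[[key]]
    else abort_validation(paste0("override key too deep: ", key))
  }
  top_bad <- setdiff(names(raw), c(PARAM_KEYS, "policy", "experiment"))
  if (length(top_bad))
    abort_validation(paste0("unknown config key(s): ",
                            paste(top_bad, collapse = ", ")))
  cfg <- run_config(params = raw[intersect(names(raw), PARAM_KEYS)],
                    policy = raw$policy %||% list(mode = "constant"),
                    experiment = raw$experiment %||% list(command = "absorb"))
  if (!quiet) {
    defaults <- character(0)
    if (is.null(raw$rho1)) defaults <- c(defaults, "rho1 = 1")
    if (is.null(raw$epsilon)) defaults <- c(defaults, "epsilon = 1e-4")
    if (is.null(raw$alpha_act)) defaults <- c(defaults, "alpha_act = alpha")
    if (length(defaults))
      message("applied defaults: ", paste(defaults, collapse = ", "))
  }
  cfg
}

#' Write a run configuration to a YAML file
#'
#' Inverse of [parse_config()]: `parse_config(write_config(cfg, f))`
#' reproduces `cfg`. Floating-point values are serialized with enough
#' precision to round-trip.
#'
#' @param config a `"run_config"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  doc <- config_snapshot(config)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

# Plain-list snapshot of a config (parameters, policy, experiment) used for
# YAML round-trips and JSON sidecars.
config_snapshot <- function(config) {
  p <- config$params
  doc <- p[PARAM_KEYS]
  doc$policy <- if (config$policy$mode == "constant")
    list(mode = "constant")
  else list(mode = "belief_linked", rho_b = config$policy$rho_b)
  doc$experiment <- config$experiment
  doc
}

fmt17 <- function(x) {
  if (is.double(x)) vapply(x, function(v) format(v, digits = 17), "")
  else x
}

# CSV writer used for all result tables: RFC-4180-style with a header row,
# doubles at 17 significant digits so exact-engine outputs reproduce
# bit-for-bit.
write_result_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt17), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_sidecar <- function(config, path, extra = list()) {
  jsonlite::write_json(c(config_snapshot(config), extra), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Execute the command described by a run configuration
#'
#' Dispatches the configured subcommand to the corresponding package
#' function and writes its results under the configured output directory
#' (default: the working directory): a CSV table per sweep or series plus a
#' JSON sidecar with the exact parameter snapshot, or a JSON result file
#' for scalar outputs. Parameters, the horizon `k_star`, residual mass and
#' wall-clock time are logged to standard error; results never go to
#' standard error, so pipelines can consume the files cleanly.
#'
#' @param config a `"run_config"` from [run_config()] or [parse_config()].
#' @return Invisibly, a named list: `value` (the main computed object) and
#'   `files` (paths written).
#' @export
run_command <- function(config) {
  stopifnot(inherits(config, "run_config"))
  exp <- config$experiment
  params <- config$params
  policy <- config$policy
  out_dir <- exp$output %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  truth <- exp$truth %||% "false"
  grid <- exp$grid %||% default_rho0_grid()
  max_k <- exp$max_k %||% 100000L
  t0 <- proc.time()[["elapsed"]]
  fp <- function(name) file.path(out_dir, name)
  files <- character(0)
  value <- switch(
    exp$command,
    "absorb" = {
      res <- absorption_probabilities(params, truth, policy, max_k)
      jsonlite::write_json(
        list(p_canonize = res$p_canonize, p_reject = res$p_reject,
             p_undecided = res$p_undecided, k_star = res$k_star,
             truth = res$truth),
        fp("absorb.json"), auto_unbox = TRUE, digits = NA)
      phi <- data.frame(k = seq_len(res$k_star),
                        phi_canonize = res$phi_canonize,
                        phi_reject = res$phi_reject)
      write_result_csv(phi, fp("first_passage.csv"))
      write_sidecar(config, fp("absorb_params.json"))
      files <- fp(c("absorb.json", "first_passage.csv", "absorb_params.json"))
      message(sprintf("absorb: k* = %d, residual = %.3g", res$k_star,
                      res$p_undecided))
      res
    },
    "simulate" = {
      est <- estimate_absorption(params, truth, policy,
                                 n_reps = exp$n_reps %||% 10000L,
                                 seed = exp$seed %||% 1L,
                                 max_experiments = exp$max_experiments %||% 1e6)
      df <- data.frame(outcome = names(est$fractions),
                       count = as.integer(est$counts),
                       fraction = as.numeric(est$fractions),
                       se = as.numeric(est$se))
      write_result_csv(df, fp("simulate.csv"))
      write_sidecar(config, fp("simulate_params.json"),
                    extra = list(n_reps = est$n_reps))
      files <- fp(c("simulate.csv", "simulate_params.json"))
      est
    },
    "sweep-rho0" = run_sweep(sweep_rho0(params, grid, max_k), config,
                             fp, "sweep_rho0"),
    "sweep-q0" = run_sweep(sweep_q0(params, exp$grid %||% default_q0_grid(),
                                    max_k), config, fp, "sweep_q0"),
    "sweep-tau" = run_sweep(sweep_tau(params, exp$tau0_values, max_k),
                            config, fp, "sweep_tau"),
    "roc" = run_sweep(roc_curve(params, grid, max_k), config, fp, "roc"),
    "drift" = run_sweep(drift_curve(params, grid), config, fp, "drift"),
    "dynamic" = run_sweep(dynamic_policy_sweep(params, grid, max_k),
                          config, fp, "dynamic"),
    "threshold" = {
      thr <- threshold_rho0(params, exp$level %||% 0.5, grid, max_k)
      jsonlite::write_json(
        list(rho0_threshold = as.numeric(thr),
             probability_level = exp$level %||% 0.5,
             grid_step = attr(thr, "grid_step"),
             p_at_threshold = attr(thr, "p_at_threshold")),
        fp("threshold.json"), auto_unbox = TRUE, digits = NA)
      write_sidecar(config, fp("threshold_params.json"))
      files <- fp(c("threshold.json", "threshold_params.json"))
      thr
    },
    "ratio" = {
      cts <- exp$counts
      if (is.null(cts) || length(cts) != 4L)
        abort_validation("'ratio' needs experiment$counts = c(pos_published, pos_total, neg_published, neg_total)")
      r <- published_rate_ratio(cts[1], cts[2], cts[3], cts[4])
      cat(sprintf("%.2f\n", r))
      jsonlite::write_json(list(percent = r, counts = as.integer(cts)),
                           fp("ratio.json"), auto_unbox = TRUE, digits = NA)
      files <- fp("ratio.json")
      r
    })
  if (exp$command %in% c("sweep-rho0", "sweep-q0", "sweep-tau", "roc",
                         "drift", "dynamic")) {
    files <- value$files
    value <- value$sweep
  }
  message(sprintf("%s finished in %.2f s", exp$command,
                  proc.time()[["elapsed"]] - t0))
  invisible(list(value = value, files = files))
}

run_sweep <- function(sw, config, fp, stem) {
  csv <- fp(paste0(stem, ".csv"))
  sidecar <- fp(paste0(stem, "_params.json"))
  write_result_csv(as.data.frame(sw), csv)
  write_sidecar(config, sidecar)
  if ("residual" %in% names(sw))
    message(sprintf("%s: %d points, max k* = %s, max residual = %.3g",
                    stem, nrow(sw), max(sw$k_star), max(sw$residual)))
  list(sweep = sw, files = c(csv, sidecar))
}
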