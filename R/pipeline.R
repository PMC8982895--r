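#' Read and validate a pipeline configuration
#'
#' Configurations are flat YAML (or an equivalent R list) with the keys:
#' exactly one of `input` (path to a long-format CSV) or `simulation`
#' (a block of [sim_config()] arguments; `seed` is mandatory); optional
#' `response` label, `relative` flag (normalize by the pre-surgery
#' baseline), `baseline_day`, `window` (min/max day plus `keep_baseline`),
#' `dictionary` (arguments of [default_dictionary()]), `gamma`, `gamma_grid`
#' ("start:stop:step"), `control` (arguments of [smm_control()]), and
#' `outdir`.
#'
#' @param config a named list or path to a YAML file.
#' @return validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim) {
    stop("config error: exactly one of 'input' and 'simulation' is required")
  }
  if (has_sim && is.null(config$simulation$seed)) {
    stop("config error: simulation block requires a seed")
  }
  if (is.null(config$gamma)) config$gamma <- 0.5
  if (is.null(config$outdir)) config$outdir <- "."
  if (is.null(config$relative)) config$relative <- FALSE
  if (is.null(config$baseline_day)) config$baseline_day <- -1
  structure(config, class = c("pipeline_config", "list"))
}

parse_gamma_grid <- function(spec) {
  if (is.numeric(spec)) return(spec)
  parts <- as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]])
  if (length(parts) != 3 || anyNA(parts)) {
    stop("config error: gamma grid must be numeric or 'start:stop:step'")
  }
  seq(parts[1], parts[2], by = parts[3])
}

# Resolve the dataset named by a pipeline config (load or simulate,
# optionally window and normalize). Returns list(data, truth or NULL).
resolve_dataset <- function(config) {
  if (!is.null(config$input)) {
    schema_default <- c(mouse_id = "mouse_id", group = "group",
                        day = "day", value = "value")
    schema <- schema_default
    if (!is.null(config$schema)) {
      schema[names(config$schema)] <- unlist(config$schema)
    }
    if (!is.null(config$response)) schema[["value"]] <- config$response
    data <- load_long_csv(config$input, schema = schema,
                          response_name = if (is.null(config$response))
                            "value" else config$response)
    truth <- NULL
  } else {
    sim_args <- config$simulation
    sim_args$seed <- as.integer(sim_args$seed)
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    data <- sim$data
    truth <- sim$truth
  }
  if (!is.null(config$window)) {
    w <- config$window
    data <- filter_time_window(data, w$min_day, w$max_day,
                               keep_baseline = isTRUE(w$keep_baseline),
                               baseline_day = config$baseline_day)
  }
  if (isTRUE(config$relative)) {
    data <- to_relative(data, baseline_day = config$baseline_day)
  }
  list(data = data, truth = truth)
}

resolved_control <- function(config) {
  ctl_args <- if (is.null(config$control)) list() else config$control
  ctl_args$gamma <- config$gamma
  do.call(smm_control, ctl_args)
}

write_run_log <- function(config, outdir, resolved) {
  log <- list(config = unclass(config), resolved = resolved,
              package_version = as.character(utils::packageVersion("smmlasso")))
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
}

#' Fit the semiparametric model and the linear baseline, writing artifacts
#'
#' Writes to the configured output directory: `fixed_effects.csv`,
#' `lambda.csv` (basis coefficients with labels), `phi.csv` (per-mouse
#' intercepts), `trajectories.csv` (dense fitted population curves for both
#' groups), `lmm_comparison.csv`, `trace.csv` (EM convergence trace) and
#' `run_log.yaml` (all resolved settings).
#'
#' @param config a [read_pipeline_config()] input (list or YAML path).
#' @return invisibly, a list with the `smm_fit`, the `lmm_fit` and the
#'   output directory.
#' @export
run_fit <- function(config) {
  config <- read_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- resolve_dataset(config)
  dict_args <- if (is.null(config$dictionary)) list() else config$dictionary
  dict <- do.call(default_dictionary,
                  c(list(times = ds$data$data$day), dict_args))
  control <- resolved_control(config)

  fit <- fit_smm(ds$data, dict, control)
  lmm <- fit_lmm(ds$data, control)

  utils::write.csv(fit$fixed_effects,
                   file.path(outdir, "fixed_effects.csv"), row.names = FALSE)
  utils::write.csv(data.frame(basis = names(fit$state$lambda),
                              lambda = fit$state$lambda),
                   file.path(outdir, "lambda.csv"), row.names = FALSE)
  utils::write.csv(data.frame(mouse_id = names(fit$design$n_i),
                              phi = fit$state$phi),
                   file.path(outdir, "phi.csv"), row.names = FALSE)
  utils::write.csv(fitted_trajectories(fit),
                   file.path(outdir, "trajectories.csv"), row.names = FALSE)
  utils::write.csv(compare_fits(fit, lmm),
                   file.path(outdir, "lmm_comparison.csv"), row.names = FALSE)
  utils::write.csv(fit$trace, file.path(outdir, "trace.csv"),
                   row.names = FALSE)
  write_run_log(config, outdir,
                list(gamma = control$gamma, dictionary_M = dict$M,
                     tol = control$tol, lasso_tol = control$lasso_tol,
                     n = ds$data$n, N = ds$data$N,
                     response = ds$data$response,
                     converged = fit$converged, iterations = fit$state$iter))
  invisible(list(smm = fit, lmm = lmm, outdir = outdir))
}

#' Run a gamma sweep and write its artifacts
#'
#' Writes `sweep.csv` (one row per grid point), `smoothness.csv`,
#' `sweep_plot.pdf` (group effect vs gamma with the significance boundary)
#' and `run_log.yaml`.
#'
#' @param config a [read_pipeline_config()] input; uses `gamma_grid`
#'   (numeric vector or "start:stop:step", default "0:2:0.05").
#' @return invisibly, the `gamma_sweep` object.
#' @export
run_sweep <- function(config) {
  config <- read_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- resolve_dataset(config)
  dict_args <- if (is.null(config$dictionary)) list() else config$dictionary
  dict <- do.call(default_dictionary,
                  c(list(times = ds$data$data$day), dict_args))
  grid <- parse_gamma_grid(if (is.null(config$gamma_grid)) "0:2:0.05"
                           else config$gamma_grid)
  control <- resolved_control(config)

  sweep <- gamma_sweep(ds$data, dict, grid = grid, control = control)
  if (all(sweep$records$failed)) {
    stop("all sweep fits failed: ",
         paste(unique(sweep$records$message), collapse = "; "))
  }
  utils::write.csv(sweep$records, file.path(outdir, "sweep.csv"),
                   row.names = FALSE)
  if (sum(!sweep$records$failed) >= 2) {
    utils::write.csv(smoothness_report(sweep),
                     file.path(outdir, "smoothness.csv"), row.names = FALSE)
  }
  ggplot2::ggsave(file.path(outdir, "sweep_plot.pdf"),
                  plot_gamma_sweep(sweep), width = 7, height = 5)
  write_run_log(config, outdir,
                list(grid = grid, dictionary_M = dict$M,
                     n = ds$data$n, N = ds$data$N,
                     response = ds$data$response,
                     failed = sum(sweep$records$failed)))
  invisible(sweep)
}

#' Simulate a dataset and write it with its generative truth
#'
#' Writes `simulated.csv` (the long-format dataset, readable by
#' [load_long_csv()]), `truth_mu.csv` (the true group mean curves on the
#' schedule), `truth_phi.csv` (realized intercepts) and `run_log.yaml`.
#'
#' @param config a [read_pipeline_config()] input with a `simulation` block
#'   (seed mandatory).
#' @return invisibly, the simulated dataset object.
#' @export
run_simulate <- function(config) {
  config <- read_pipeline_config(config)
  if (is.null(config$simulation)) {
    stop("config error: run_simulate requires a simulation block")
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- config$simulation
  sim_args$seed <- as.integer(sim_args$seed)
  cfg <- do.call(sim_config, sim_args)
  sim <- simulate_dataset(cfg)

  write_long_csv(sim$data, file.path(outdir, "simulated.csv"))
  grid <- sim$truth$grid
  utils::write.csv(
    data.frame(group = rep(c(0, 1), each = length(grid)),
               day = rep(grid, 2),
               mu = c(sim$truth$mu[[1]](grid), sim$truth$mu[[2]](grid))),
    file.path(outdir, "truth_mu.csv"), row.names = FALSE)
  utils::write.csv(data.frame(mouse_id = names(sim$truth$phi),
                              phi = unname(sim$truth$phi)),
                   file.path(outdir, "truth_phi.csv"), row.names = FALSE)
  write_run_log(config, outdir,
                list(seed = cfg$seed, n = sim$data$n, N = sim$data$N))
  invisible(sim)
}
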